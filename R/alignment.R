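#' Algorithm configuration
#'
#' Collects the tunable constants of the inference procedure. Defaults are the
#' operating values used throughout: columns are dropped when more than 15\%
#' of the weighted sequences are gapped; a sequence aligning at most 50\% of
#' the sites expected present in its (candidate) subtree's ancestor is a
#' fragment, unless its subtree already holds at least three other sequences;
#' and a previously dated duplication is revised only when the focal group is
#' closer to the candidate orthologs than to the established paralogs by more
#' than 1.5 (no-duplication alternative) or 0.5 (duplication alternative)
#' summed standard deviations of the two distances.
#'
#' @param gap_threshold Maximum weighted gap fraction for a kept column.
#' @param fragment_coverage Coverage fraction at or below which a sequence is
#'   flagged as a fragment.
#' @param fragment_exempt_os_size Number of \emph{other} sequences in a
#'   subtree that exempts its members from the fragment test.
#' @param ortholog_sd_multiplier Significance multiplier when the alternative
#'   hypothesis implies no duplication.
#' @param paralog_sd_multiplier Significance multiplier when the alternative
#'   implies a duplication.
#' @param alphabet_states Number of character states for the Jukes-Cantor
#'   correction (20 for proteins).
#' @param max_distance Cap substituted for saturated corrected distances.
#' @param revision_literal_sign Use the literal printed orientation of the
#'   revision inequality (\code{dist1 - dist2 > m*(sd1 + sd2)} with
#'   \code{dist1} the distance to the candidate orthologs) instead of the
#'   default orientation in which the merge is favored when the focal group is
#'   significantly \emph{closer} to the candidate orthologs.
#' @return A list of class \code{giga_config}.
#' @export
giga_config <- function(gap_threshold = 0.15,
                        fragment_coverage = 0.5,
                        fragment_exempt_os_size = 3L,
                        ortholog_sd_multiplier = 1.5,
                        paralog_sd_multiplier = 0.5,
                        alphabet_states = 20L,
                        max_distance = 5,
                        revision_literal_sign = FALSE) {
  stopifnot(gap_threshold > 0, gap_threshold < 1,
            fragment_coverage > 0, fragment_coverage < 1,
            fragment_exempt_os_size >= 1,
            ortholog_sd_multiplier > 0, paralog_sd_multiplier > 0,
            alphabet_states >= 2, max_distance > 0)
  structure(list(gap_threshold = gap_threshold,
                 fragment_coverage = fragment_coverage,
                 fragment_exempt_os_size = as.integer(fragment_exempt_os_size),
                 ortholog_sd_multiplier = ortholog_sd_multiplier,
                 paralog_sd_multiplier = paralog_sd_multiplier,
                 alphabet_states = as.integer(alphabet_states),
                 max_distance = max_distance,
                 revision_literal_sign = isTRUE(revision_literal_sign)),
            class = "giga_config")
}

# Characters treated as non-informative for both trimming and distances.
# Ambiguity codes are conservatively handled like gaps.
GAP_CHARS <- c("-", ".", "X", "B", "Z", "*")

#' Read an aligned protein family from FASTA
#'
#' All sequences must have equal aligned length, with \code{'-'} as the gap
#' character. The species of each sequence is taken from the identifier
#' suffix after the final underscore (the 5-letter UniProt code convention,
#' e.g. \code{MTHFR_HUMAN}), unless a two-column \code{species_map} overrides
#' it.
#'
#' @param path FASTA file of aligned sequences.
#' @param species_map Optional: a named character vector (names = sequence
#'   ids, values = species codes) or the path of a two-column TSV file.
#' @return An object of class \code{family_alignment}: a list with
#'   \code{matrix} (character matrix, rows = sequences), \code{ids},
#'   \code{species} and \code{length}.
#' @export
read_family_alignment <- function(path, species_map = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  family_alignment(stats::setNames(as.character(aa), ids),
                   species_map = species_map)
}

#' Build a family alignment from named aligned strings
#'
#' @param seqs Named character vector of aligned residue strings.
#' @param species_map As in \code{\link{read_family_alignment}}.
#' @return A \code{family_alignment}.
#' @export
family_alignment <- function(seqs, species_map = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must carry unique, nonempty identifiers")
  if (length(seqs) == 0L) stop("empty alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length")
  if (is.character(species_map) && length(species_map) == 1L &&
      file.exists(species_map)) {
    tab <- utils::read.table(species_map, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("id", "species"))
    species_map <- stats::setNames(tab$species, tab$id)
  }
  species <- if (is.null(species_map)) species_from_id(ids)
             else unname(species_map[ids])
  if (anyNA(species) || any(!nzchar(species)))
    stop("species unresolvable for: ",
         paste(ids[is.na(species) | !nzchar(species)], collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- ids
  structure(list(matrix = mat, ids = ids,
                 species = stats::setNames(species, ids),
                 length = unique(lens)),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("Family alignment: %d sequences x %d columns, %d species\n",
              length(x$ids), x$length, length(unique(x$species))))
  invisible(x)
}

#' Position-based sequence weights
#'
#' Henikoff-style position-based weighting: at each column, each observed
#' residue shares weight \code{1/(r*s)} among the \code{s} sequences
#' carrying it, where \code{r} is the number of distinct residues in the
#' column; gapped sequences contribute (and receive) nothing at that column.
#' Per-sequence weights are the sums over columns, normalized to sum to the
#' number of sequences. Redundant (identical) sequences are thereby
#' down-weighted and receive identical weights; divergent sequences are
#' up-weighted. The weights feed only the gap-trimming threshold.
#'
#' @param aln A \code{family_alignment}.
#' @return Named numeric vector of weights summing to the sequence count.
#' @export
compute_weights <- function(aln) {
  mat <- aln$matrix
  n <- nrow(mat)
  if (n == 1L) return(stats::setNames(1, aln$ids))
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- !(col %in% GAP_CHARS)
    if (!any(res)) next
    counts <- table(col[res])
    r <- length(counts)
    w[res] <- w[res] + 1 / (r * as.numeric(counts[col[res]]))
  }
  if (all(w == 0)) w <- rep(1, n)
  w[w == 0] <- min(w[w > 0]) * 1e-3 # e.g. an all-gap sequence stays > 0
  stats::setNames(w * n / sum(w), aln$ids)
}

#' Trim alignment columns by weighted gap fraction
#'
#' A column is kept iff the summed weight of sequences gapped at it is at
#' most \code{cfg$gap_threshold} of the total weight. Ambiguity characters
#' count as gaps. Trimming is idempotent.
#'
#' @param aln A \code{family_alignment}.
#' @param weights Named weights from \code{\link{compute_weights}}; computed
#'   when \code{NULL}.
#' @param cfg A \code{\link{giga_config}}.
#' @return A \code{trimmed_alignment}: the restricted alignment plus
#'   \code{kept_columns}, the original column indices retained.
#' @export
trim_alignment <- function(aln, weights = NULL, cfg = giga_config()) {
  if (is.null(weights)) weights <- compute_weights(aln)
  w <- unname(weights[aln$ids])
  if (anyNA(w)) stop("weights must cover every sequence")
  gapped <- aln$matrix %in% GAP_CHARS
  dim(gapped) <- dim(aln$matrix)
  gap_frac <- as.numeric(crossprod(gapped, w)) / sum(w)
  kept <- which(gap_frac <= cfg$gap_threshold)
  structure(list(matrix = aln$matrix[, kept, drop = FALSE],
                 ids = aln$ids, species = aln$species,
                 kept_columns = kept, length = length(kept)),
            class = c("trimmed_alignment", "family_alignment"))
}

#' Raw pairwise p-distances over homologous sites
#'
#' For each sequence pair, \code{n} is the number of kept columns where both
#' sequences carry a residue (gaps and ambiguity codes never count as matches
#' or mismatches) and \code{p} is the fraction of those columns at which the
#' residues differ. These raw distances drive the entire agglomeration; they
#' are computed once and never updated.
#'
#' @param trimmed A \code{trimmed_alignment}.
#' @return A \code{distance_matrix}: list with symmetric matrices \code{p}
#'   and \code{n} and logical \code{no_overlap} flagging pairs with
#'   \code{n = 0} (for which \code{p} is set to 0).
#' @export
pairwise_distances <- function(trimmed) {
  mat <- trimmed$matrix
  k <- nrow(mat)
  if (k < 2L) stop("need at least two sequences")
  res <- !(mat %in% GAP_CHARS)
  dim(res) <- dim(mat)
  # integer-code residues so mismatches vectorize
  code <- matrix(match(mat, c(LETTERS)), nrow = k)
  p <- matrix(0, k, k, dimnames = list(trimmed$ids, trimmed$ids))
  n <- matrix(0L, k, k, dimnames = list(trimmed$ids, trimmed$ids))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    both <- res[i, ] & res[j, ]
    nn <- sum(both)
    pp <- if (nn > 0) sum(code[i, both] != code[j, both]) / nn else 0
    p[i, j] <- p[j, i] <- pp
    n[i, j] <- n[j, i] <- nn
  }
  structure(list(p = p, n = n,
                 no_overlap = (n == 0) & !diag(k),
                 ids = trimmed$ids),
            class = "distance_matrix")
}

#' Jukes-Cantor corrected distance
#'
#' The s-state generalization \code{d = -((s-1)/s) * log(1 - (s/(s-1)) * p)}
#' of the Jukes-Cantor correction, with \code{s = 20} for amino acids. The
#' correction converts an observed fraction of differing sites into expected
#' substitutions per site under an equal-rates model; \code{d >= p} always,
#' with equality only at \code{p = 0}.
#'
#' @param p Observed difference fraction(s), in \code{[0, (s-1)/s)}.
#' @param alphabet_states Number of states \code{s}.
#' @return Corrected distance(s).
#' @export
jc_distance <- function(p, alphabet_states = 20L) {
  s <- alphabet_states
  stopifnot(s >= 2, all(p >= 0))
  if (any(p >= (s - 1) / s))
    stop("p-distance at or beyond the Jukes-Cantor saturation bound (",
         (s - 1), "/", s, ")")
  -((s - 1) / s) * log(1 - (s / (s - 1)) * p)
}

#' Standard deviation of the Jukes-Cantor distance
#'
#' \code{sd = sqrt( p*(1-p) / ( n * (1 - (s/(s-1))*p)^2 ) )} for a distance
#' estimated from \code{n} compared sites. This uncertainty backs the
#' significance test that decides whether a previously dated duplication may
#' be revised.
#'
#' @param p Observed difference fraction(s).
#' @param n Number of compared sites (>= 1).
#' @param alphabet_states Number of states \code{s}.
#' @return Standard deviation(s).
#' @export
jc_stddev <- function(p, n, alphabet_states = 20L) {
  s <- alphabet_states
  if (any(n < 1)) stop("undefined uncertainty: no compared sites")
  stopifnot(all(p >= 0))
  if (any(p >= (s - 1) / s))
    stop("p-distance at or beyond the Jukes-Cantor saturation bound")
  sqrt(p * (1 - p) / (n * (1 - (s / (s - 1)) * p)^2))
}

#' Write aligned sequences to FASTA
#'
#' @param aln A \code{family_alignment} or \code{trimmed_alignment}.
#' @param path Output file path.
#' @export
write_family_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(seqs, aln$ids)), path)
  invisible(path)
}
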