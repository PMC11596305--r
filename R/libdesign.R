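#' Sequence pool with a fragment boundary
#'
#' A set of unique, equal-length amino-acid sequences together with the
#' fragment boundary used for two-fragment library assembly: fragment 1 is
#' positions 1..boundary, fragment 2 is boundary+1..end (the assembly
#' scheme that splits the binder at L55/D56).
#'
#' @param sequences character vector of unique equal-length sequences.
#' @param boundary last position of fragment 1; strictly inside the length.
#' @return a `SequencePool`.
#' @export
sequence_pool <- function(sequences, boundary) {
  if (!length(sequences)) stop("empty sequence pool")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("pool sequences must all have equal length")
  if (anyDuplicated(sequences)) stop("pool sequences must be unique")
  boundary <- as.integer(boundary)
  if (boundary < 1L || boundary >= len)
    stop("boundary must be strictly inside the sequence (1 <= b < length)")
  out <- list(sequences = sequences, boundary = boundary, length = len)
  class(out) <- "SequencePool"
  out
}

#' Split a pool into two fragment oligo pools
#'
#' Cuts every sequence at the boundary and collects the unique fragment-1
#' and fragment-2 sequences. The library degeneracy is the product of the
#' two pool sizes; every input sequence is reconstructible as a fragment-1
#' member concatenated with a fragment-2 member.
#'
#' @param pool a [sequence_pool()].
#' @return `OligoPools`: list(pool1, pool2, degeneracy).
#' @export
split_into_fragment_pools <- function(pool) {
  stopifnot(inherits(pool, "SequencePool"))
  f1 <- unique(substr(pool$sequences, 1L, pool$boundary))
  f2 <- unique(substr(pool$sequences, pool$boundary + 1L, pool$length))
  out <- list(pool1 = f1, pool2 = f2,
              degeneracy = max_degeneracy(length(f1), length(f2)))
  class(out) <- "OligoPools"
  out
}

#' @export
print.OligoPools <- function(x, ...) {
  cat(sprintf("OligoPools: %d x %d fragments, degeneracy %s\n",
              length(x$pool1), length(x$pool2),
              format(x$degeneracy, big.mark = ",")))
  invisible(x)
}

#' Maximum degeneracy of a two-pool combinatorial library
#'
#' @param pool1_size,pool2_size unique fragment counts (>= 0).
#' @return product of the sizes.
#' @export
max_degeneracy <- function(pool1_size, pool2_size) {
  if (pool1_size < 0 || pool2_size < 0) stop("pool sizes must be >= 0")
  as.numeric(pool1_size) * as.numeric(pool2_size)
}

#' Size of a combinatorial mutational space
#'
#' Number of sequences reachable when `n_mutable` positions can each take
#' any of `alphabet_size` letters (e.g. 11 positions over the 17
#' proteinogenic amino acids excluding G, P and C).
#'
#' @param n_mutable number of mutable positions (>= 0).
#' @param alphabet_size alphabet size (>= 1).
#' @return alphabet_size ^ n_mutable, as a double.
#' @export
mutational_space_size <- function(n_mutable = 11, alphabet_size = 17) {
  if (n_mutable < 0 || alphabet_size < 1)
    stop("need n_mutable >= 0 and alphabet_size >= 1")
  out <- as.numeric(alphabet_size)^as.numeric(n_mutable)
  if (out > 2^53) warning("count exceeds exact double-precision integers")
  out
}

#' Per-position symbol frequencies (consensus logo counts)
#'
#' @param sequences equal-length sequences.
#' @param positions positions to tabulate (default: all).
#' @return list with `counts` and `freqs`: position-indexed lists of named
#'   vectors; counts sum to the number of sequences, freqs to 1.
#' @export
consensus_counts <- function(sequences, positions = NULL) {
  if (!length(sequences)) stop("empty sequence set")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("sequences must have equal length")
  if (is.null(positions)) positions <- seq_len(len)
  if (any(positions < 1 | positions > len))
    stop("positions outside sequence length")
  mat <- do.call(rbind, strsplit(sequences, ""))
  counts <- lapply(positions, function(p) table(mat[, p]))
  counts <- lapply(counts, function(tb) {
    v <- as.integer(tb); names(v) <- names(tb); v
  })
  names(counts) <- positions
  freqs <- lapply(counts, function(v) v / sum(v))
  list(counts = counts, freqs = freqs)
}

#' Plate-screen Z-scores of density-normalized luminescence
#'
#' Normalizes each well's luminescence by its cell density (OD600) and
#' standardizes the normalized signal per condition using the condition
#' mean and sample SD. Conditions whose normalized signals are constant
#' (SD = 0) are flagged degenerate and given z = 0.
#'
#' @param wells data.frame with columns `condition`, `od600`,
#'   `luminescence` (and optionally `well`).
#' @return the input with added columns `normalized`, `z`, and attribute
#'   `degenerate_conditions`.
#' @export
plate_zscores <- function(wells) {
  need <- c("condition", "od600", "luminescence")
  if (!all(need %in% names(wells)))
    stop("wells must have columns ", paste(need, collapse = ", "))
  if (any(wells$od600 <= 0)) stop("OD600 must be > 0 for every well")
  wells$normalized <- wells$luminescence / wells$od600
  wells$z <- NA_real_
  degen <- character(0)
  for (cond in unique(wells$condition)) {
    i <- wells$condition == cond
    if (sum(i) < 2)
      stop("condition '", cond, "' has fewer than 2 wells; SD undefined")
    s <- stats::sd(wells$normalized[i])
    if (s == 0) {
      wells$z[i] <- 0
      degen <- c(degen, cond)
    } else {
      wells$z[i] <- (wells$normalized[i] - mean(wells$normalized[i])) / s
    }
  }
  attr(wells, "degenerate_conditions") <- degen
  wells
}

#' FACS gate selection and screening-coverage check
#'
#' Selects the top `fraction` of events (ceil(N x fraction) highest values;
#' ties at the threshold are included) and checks the coverage rule that at
#' least `factor` times more events were screened than the library
#' complexity.
#'
#' @param values per-event signal values.
#' @param fraction gate fraction (default 0.001, i.e. top 0.1%).
#' @param events total events screened.
#' @param complexity library complexity (>= 1).
#' @param factor required coverage multiple (default 20).
#' @return list(threshold, selected (indices), n_target, coverage,
#'   coverage_ok).
#' @export
gate_and_coverage <- function(values, fraction = 0.001,
                              events = length(values), complexity,
                              factor = 20) {
  if (!length(values)) stop("values must be non-empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (complexity < 1) stop("complexity must be >= 1")
  n_target <- ceiling(length(values) * fraction)
  threshold <- sort(values, decreasing = TRUE)[n_target]
  selected <- which(values >= threshold)
  coverage <- events / complexity
  list(threshold = threshold, selected = selected, n_target = n_target,
       coverage = coverage, coverage_ok = coverage >= factor)
}

#' Read/write amino-acid pools as FASTA
#'
#' Thin wrappers over Biostrings for the pool exchange format.
#'
#' @param path FASTA file.
#' @return character vector of sequences (names preserved).
#' @export
read_pool_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
    stats::setNames(as.character(seqs), sub("^>", "", lines[hdr]))
  }
}

#' @rdname read_pool_fasta
#' @param sequences named character vector of sequences.
#' @export
write_pool_fasta <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  writeLines(paste0(">", nm, "\n", sequences), path)
  invisible(path)
}
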