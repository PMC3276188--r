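#' Most-parsimonious founder-mosaic decomposition
#'
#' Decomposes an observed haplotype into segments copied from founder
#' haplotypes using the minimum number h of crossover switches. The minimum is
#' found by dynamic programming over the ordered markers: the best score for a
#' mosaic ending in founder f at marker i either stays on f or pays one switch
#' from the best founder at marker i - 1, and a founder is only allowed where
#' its allele set contains the observed allele.
#'
#' Orphan markers (allele in no founder, i.e. presumed rare mutations) are
#' handled per `orphan_policy`:
#' \describe{
#'   \item{"mutation"}{treat the marker as a wildcard and record it in
#'     `orphan_markers` (default; mirrors scoring rare alleles as mutations).}
#'   \item{"wildcard"}{treat as wildcard silently.}
#'   \item{"error"}{refuse the haplotype.}
#' }
#'
#' @param compat a `compat_matrix` from [build_compatibility()].
#' @param orphan_policy one of "mutation", "wildcard", "error".
#' @return An object of class `mosaic_decomposition`:
#' \describe{
#'   \item{h}{minimum number of switches (non-negative integer).}
#'   \item{segments}{data.frame with 1-based inclusive marker ranges
#'     (`start`, `end`), the founder chosen on one optimal path (`founder`)
#'     and the full set of founders compatible across the segment
#'     (`candidates`, a list column).}
#'   \item{breakpoints}{data.frame with, for each of the h switches, the
#'     inclusive range `[first, last]` of inter-marker intervals in which the
#'     crossover may lie (interval j separates markers j and j + 1).}
#'   \item{orphan_markers}{markers treated as wildcards.}
#' }
#' @examples
#' fd <- read_founder_table(system.file("extdata",
#'   "mauritian_mhc_founders.tsv", package = "mhcrec"))
#' h <- founder_haplotype(fd$founders, "H3")
#' min_recombinations(build_compatibility(fd$panel, fd$founders, h))$h  # 0
#' @export
min_recombinations <- function(compat,
                               orphan_policy = c("mutation", "wildcard",
                                                 "error")) {
  stopifnot(inherits(compat, "compat_matrix"))
  orphan_policy <- match.arg(orphan_policy)
  cm <- compat$matrix
  m <- nrow(cm)
  nf <- ncol(cm)
  founders <- colnames(cm)
  orphan <- compat$orphan
  if (any(orphan)) {
    if (orphan_policy == "error")
      stop("allele at marker(s) ", paste(rownames(cm)[orphan], collapse = ", "),
           " matches no founder")
    cm[orphan, ] <- TRUE
  }
  orphan_markers <- rownames(cm)[orphan]

  pen <- ifelse(cm, 0, Inf)
  # forward DP: fwd[i, f] = min switches over prefixes 1..i ending on f
  fwd <- matrix(Inf, m, nf)
  fwd[1, ] <- pen[1, ]
  if (m > 1) for (i in 2:m) {
    best_prev <- min(fwd[i - 1, ])
    fwd[i, ] <- pen[i, ] + pmin(fwd[i - 1, ], best_prev + 1)
  }
  h <- min(fwd[m, ])

  # traceback, preferring to stay on the current founder (maximal-right runs)
  path <- integer(m)
  path[m] <- which(fwd[m, ] == h)[1L]
  if (m > 1) for (i in (m - 1):1) {
    f <- path[i + 1]
    stay <- fwd[i, f] + pen[i + 1, f]
    if (is.finite(stay) && stay == fwd[i + 1, f]) {
      path[i] <- f
    } else {
      g <- which(fwd[i, ] == fwd[i + 1, f] - pen[i + 1, f] - 1)
      path[i] <- g[g != f][1L]
    }
  }

  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  candidates <- lapply(seq_along(starts), function(s) {
    rows <- starts[s]:ends[s]
    founders[colSums(!cm[rows, , drop = FALSE]) == 0L]
  })
  segments <- data.frame(start = starts, end = ends,
                         founder = founders[runs$values],
                         stringsAsFactors = FALSE)
  segments$candidates <- candidates

  # breakpoint intervals: crossover interval j keeps markers <= j on the left
  # founder and markers > j on the right one; slide j while both stay compatible
  nseg <- nrow(segments)
  if (nseg > 1) {
    first <- last <- integer(nseg - 1)
    for (s in seq_len(nseg - 1)) {
      fl <- runs$values[s]; fr <- runs$values[s + 1]
      j <- ends[s]
      hi <- j
      while (hi + 1 <= ends[s + 1] - 1 && cm[hi + 1, fl]) hi <- hi + 1
      lo <- j
      while (lo - 1 >= starts[s] && cm[lo, fr]) lo <- lo - 1
      first[s] <- lo; last[s] <- hi
    }
    breakpoints <- data.frame(first = first, last = last)
  } else {
    breakpoints <- data.frame(first = integer(0), last = integer(0))
  }

  structure(list(h = as.integer(h), segments = segments,
                 breakpoints = breakpoints, orphan_markers = orphan_markers,
                 hap = compat$hap),
            class = "mosaic_decomposition")
}

#' @export
print.mosaic_decomposition <- function(x, ...) {
  cat("Founder mosaic: h =", x$h, "switch(es)\n")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  markers %d..%d: %s (candidates: %s)\n",
                x$segments$start[i], x$segments$end[i], x$segments$founder[i],
                paste(x$segments$candidates[[i]], collapse = "/")))
  if (length(x$orphan_markers))
    cat("  orphan markers (scored as mutations):",
        paste(x$orphan_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Recombination-count spectrum
#'
#' Container for the counts n_k of haplotypes classified with exactly k
#' recombinations, the data of the Poisson fit.
#'
#' @param counts non-negative counts for k = 0, 1, ..., in order.
#' @param types optional counts of distinct haplotype types per k.
#' @return Object of class `recomb_spectrum` with elements `k`, `counts`,
#'   `n` (total) and optionally `types`.
#' @examples
#' recomb_spectrum(c(1030, 382, 74, 14))
#' @export
recomb_spectrum <- function(counts, types = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 0) || anyNA(counts))
    stop("'counts' must be non-negative and non-missing")
  n <- sum(counts)
  if (n <= 0) stop("the spectrum must contain at least one haplotype")
  structure(list(k = seq_along(counts) - 1L, counts = counts, n = n,
                 types = types),
            class = "recomb_spectrum")
}

#' @export
print.recomb_spectrum <- function(x, ...) {
  df <- data.frame(k = x$k, n_k = x$counts)
  if (!is.null(x$types)) df$types <- x$types
  cat("Recombination-count spectrum (n =", x$n, "haplotypes):\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Classify a population of phased haplotypes
#'
#' Runs [min_recombinations()] on every haplotype and tallies the spectrum
#' n_k = number of haplotypes with minimum recombination count k, together
#' with the number of distinct haplotype types per k (identical allele
#' vectors collapsed).
#'
#' @param panel a [marker_panel()].
#' @param founders a [founder_set()].
#' @param haps matrix of phased haplotypes (rows = haplotypes, columns =
#'   panel markers; NA = missing), or a list of allele vectors.
#' @param orphan_policy passed to [min_recombinations()].
#' @param max_missing haplotypes with a higher fraction of missing markers
#'   are rejected with an error (default 0.5).
#' @param keep_decompositions keep the per-haplotype
#'   `mosaic_decomposition` objects (needed for
#'   [flanking_founder_distribution()]).
#' @return A `recomb_spectrum`; if `keep_decompositions` the decompositions
#'   are attached as attribute `"decompositions"`.
#' @export
classify_population <- function(panel, founders, haps,
                                orphan_policy = "mutation",
                                max_missing = 0.5,
                                keep_decompositions = FALSE) {
  if (is.list(haps) && !is.data.frame(haps))
    haps <- do.call(rbind, haps)
  if (is.data.frame(haps)) haps <- as.matrix(haps)
  if (is.null(dim(haps))) haps <- matrix(haps, nrow = 1)
  if (nrow(haps) == 0L) stop("no haplotypes to classify")
  miss <- rowMeans(is.na(haps))
  if (any(miss > max_missing))
    stop(sum(miss > max_missing), " haplotype(s) exceed the missing-data ",
         "threshold of ", max_missing)
  dec <- vector("list", nrow(haps))
  hs <- integer(nrow(haps))
  for (i in seq_len(nrow(haps))) {
    d <- min_recombinations(build_compatibility(panel, founders, haps[i, ]),
                            orphan_policy = orphan_policy)
    hs[i] <- d$h
    if (keep_decompositions) dec[[i]] <- d
  }
  kmax <- max(hs)
  counts <- tabulate(hs + 1L, nbins = kmax + 1L)
  keys <- apply(haps, 1, paste, collapse = ",")
  types <- vapply(0:kmax, function(k) length(unique(keys[hs == k])),
                  integer(1))
  sp <- recomb_spectrum(counts, types = types)
  if (keep_decompositions) attr(sp, "decompositions") <- dec
  sp
}

#' Founder frequencies at the flanks of recombinant haplotypes
#'
#' For single recombinants (h = 1) the telomeric part is the first mosaic
#' segment and the centromeric part the last; for double recombinants (h = 2)
#' the central part is the middle segment. Founder assignment at a flank can
#' be ambiguous when alleles are shared between founders; ties are either
#' spread fractionally over the candidate founders (default) or the ambiguous
#' haplotype is dropped.
#'
#' @param decompositions list of `mosaic_decomposition` objects, all with the
#'   h required by `part` (h >= 1 for the flanks, h = 2 for "central").
#' @param part which segment to tally.
#' @param founders character vector of founder ids fixing the output order
#'   (defaults to the union seen in the decompositions).
#' @param ties "fractional" or "drop".
#' @return Named numeric vector of (possibly fractional) counts per founder,
#'   summing to the number of usable decompositions.
#' @export
flanking_founder_distribution <- function(decompositions,
                                          part = c("telomeric", "central",
                                                   "centromeric"),
                                          founders = NULL,
                                          ties = c("fractional", "drop")) {
  part <- match.arg(part)
  ties <- match.arg(ties)
  if (length(decompositions) == 0L) stop("no decompositions supplied")
  hs <- vapply(decompositions, `[[`, integer(1), "h")
  if (part == "central") {
    if (any(hs != 2L))
      stop("the central part is only defined for double recombinants (h = 2)")
  } else if (any(hs < 1L)) {
    stop("flanking parts are only defined for recombinants (h >= 1)")
  }
  if (is.null(founders))
    founders <- unique(unlist(lapply(decompositions, function(d)
      unlist(d$segments$candidates))))
  out <- stats::setNames(numeric(length(founders)), founders)
  for (d in decompositions) {
    seg <- switch(part,
                  telomeric = 1L,
                  centromeric = nrow(d$segments),
                  central = 2L)
    cand <- d$segments$candidates[[seg]]
    if (length(cand) == 0L) cand <- d$segments$founder[seg]
    if (length(cand) > 1L && ties == "drop") next
    out[cand] <- out[cand] + 1 / length(cand)
  }
  out
}

#' Pearson chi-squared homogeneity test against reference frequencies
#'
#' Compares an observed count vector with expected counts n * reference, as
#' used to ask whether the founders flanking recombination breakpoints are
#' drawn from the same distribution as the intact founding haplotypes.
#'
#' @param observed non-negative counts per category.
#' @param reference reference frequencies (same length, summing to 1).
#' @return List with `statistic`, `df` (categories - 1) and `p_value`
#'   (upper tail).
#' @examples
#' homogeneity_chi2(c(10, 0), c(0.5, 0.5))  # statistic 10, df 1
#' @export
homogeneity_chi2 <- function(observed, reference) {
  if (length(observed) != length(reference))
    stop("'observed' and 'reference' must have the same length")
  if (any(observed < 0) || anyNA(observed) || anyNA(reference))
    stop("counts and frequencies must be non-negative and non-missing")
  if (abs(sum(reference) - 1) > 1e-8)
    stop("'reference' frequencies must sum to 1")
  if (any(reference == 0 & observed > 0))
    stop("nonzero observed count in a category with zero reference frequency")
  keep <- reference > 0
  observed <- observed[keep]; reference <- reference[keep]
  n <- sum(observed)
  expected <- n * reference
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}
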