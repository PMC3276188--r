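#' Ordered marker panel
#'
#' Defines the coordinate axis of the haplotype: an ordered set of
#' microsatellite markers, conventionally listed telomere to centromere.
#'
#' @param markers character vector of unique marker names, in map order.
#' @param positions optional numeric physical coordinates (bp), same order,
#'   strictly increasing.
#' @return An object of class `marker_panel`.
#' @examples
#' marker_panel(c("D6S2972", "D6S2970", "D6S2854"))
#' @export
marker_panel <- function(markers, positions = NULL) {
  markers <- as.character(markers)
  if (length(markers) == 0L) stop("a marker panel needs at least one marker")
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (!is.null(positions)) {
    positions <- as.numeric(positions)
    if (length(positions) != length(markers))
      stop("'positions' must have one entry per marker")
    if (any(diff(positions) <= 0))
      stop("'positions' must be strictly increasing along the panel")
  }
  structure(list(markers = markers, positions = positions),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", length(x$markers), "markers (telomere -> centromere)\n")
  cat(" ", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.marker_panel <- function(x) length(x$markers)

#' Founder haplotype set
#'
#' Holds, for each founder haplotype and each marker of the panel, the set of
#' allele lengths (integer bp) compatible with that founder. Multi-allele
#' cells arise from within-founder microsatellite variants (scored as
#' mutations) and from co-amplified fragments.
#'
#' @param panel a [marker_panel()].
#' @param alleles a list with one element per founder (named by founder id);
#'   each element is a list of integer vectors, one non-empty vector per
#'   marker, in panel order (names, if present, must match the panel).
#' @return An object of class `founder_set` with elements `panel`,
#'   `founders` (ids) and `alleles` (list indexed `[[founder]][[marker]]`).
#' @seealso [read_founder_table()] to build one from a TSV file.
#' @export
founder_set <- function(panel, alleles) {
  stopifnot(inherits(panel, "marker_panel"))
  if (length(alleles) == 0L) stop("at least one founder is required")
  ids <- names(alleles)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("'alleles' must be a named list with unique founder ids")
  m <- length(panel$markers)
  alleles <- lapply(alleles, function(f) {
    if (length(f) != m)
      stop("each founder must define alleles at every marker of the panel")
    if (!is.null(names(f)) && !identical(names(f), panel$markers))
      f <- f[panel$markers]
    f <- lapply(f, function(a) {
      a <- as.integer(a)
      if (length(a) == 0L || anyNA(a) || any(a <= 0L))
        stop("allele sets must be non-empty positive integers")
      unique(a)  # keep input order: the first allele is the primary one
    })
    names(f) <- panel$markers
    f
  })
  structure(list(panel = panel, founders = ids, alleles = alleles),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("Founder set:", length(x$founders), "founders (",
      paste(x$founders, collapse = ", "), ") over",
      length(x$panel$markers), "markers\n")
  invisible(x)
}

#' Extract a founder's haplotype as an allele vector
#'
#' Returns the first-listed allele at each marker: the primary allele of a
#' possibly multi-allele founder cell (secondary alleles are minor
#' within-founder variants or co-amplified fragments).
#'
#' @param founders a [founder_set()].
#' @param id founder id.
#' @return Named integer vector over the panel markers.
#' @export
founder_haplotype <- function(founders, id) {
  stopifnot(inherits(founders, "founder_set"))
  if (!id %in% founders$founders) stop("unknown founder id: ", id)
  vapply(founders$alleles[[id]], `[[`, integer(1), 1L)
}

#' Marker-by-founder compatibility of an observed haplotype
#'
#' For one phased haplotype, records which founders carry a compatible allele
#' at each marker. A missing allele (NA) is uninformative and compatible with
#' every founder. A marker whose allele matches no founder is flagged as an
#' "orphan" (typically a rare mutant allele).
#'
#' @param panel a [marker_panel()].
#' @param founders a [founder_set()] defined on the same panel.
#' @param hap integer vector of allele lengths over the panel (NA = missing).
#'   If named, names must match the panel markers (any order).
#' @return An object of class `compat_matrix`: a list with `matrix` (logical,
#'   markers x founders), `orphan` (logical per marker), `missing` (logical
#'   per marker) and `hap` (the aligned allele vector).
#' @examples
#' fd <- read_founder_table(system.file("extdata",
#'   "mauritian_mhc_founders.tsv", package = "mhcrec"))
#' h1 <- founder_haplotype(fd$founders, "H1")
#' cm <- build_compatibility(fd$panel, fd$founders, h1)
#' all(cm$matrix[, "H1"])
#' @export
build_compatibility <- function(panel, founders, hap) {
  stopifnot(inherits(panel, "marker_panel"), inherits(founders, "founder_set"))
  if (!identical(founders$panel$markers, panel$markers))
    stop("founder set is not defined on this panel")
  m <- length(panel$markers)
  if (!is.null(names(hap))) {
    if (!setequal(names(hap), panel$markers))
      stop("haplotype marker names do not match the panel")
    hap <- hap[panel$markers]
  }
  if (length(hap) != m)
    stop("haplotype has ", length(hap), " markers; panel has ", m)
  hap <- as.integer(hap)
  cm <- matrix(FALSE, nrow = m, ncol = length(founders$founders),
               dimnames = list(panel$markers, founders$founders))
  for (f in founders$founders) {
    sets <- founders$alleles[[f]]
    cm[, f] <- vapply(seq_len(m), function(i)
      is.na(hap[i]) || hap[i] %in% sets[[i]], logical(1))
  }
  orphan <- rowSums(cm) == 0L
  structure(list(matrix = cm, orphan = orphan, missing = is.na(hap),
                 hap = stats::setNames(hap, panel$markers)),
            class = "compat_matrix")
}
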