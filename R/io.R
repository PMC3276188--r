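#' Read a founder-haplotype table
#'
#' Parses a TSV with the marker name in the first column (one row per marker,
#' telomere to centromere) and one column per founder. A cell may hold
#' several compatible alleles separated by commas, en-dashes or whitespace
#' (e.g. "173,193" or "173-193"); parentheses around minor variants are
#' ignored. Lines starting with `#` are comments.
#'
#' @param path path to the TSV file.
#' @return List with `panel` (a [marker_panel()]) and `founders`
#'   (a [founder_set()]).
#' @examples
#' fd <- read_founder_table(system.file("extdata",
#'   "mauritian_mhc_founders.tsv", package = "mhcrec"))
#' length(fd$panel$markers)  # 17
#' @export
read_founder_table <- function(path) {
  if (!file.exists(path)) stop("founder table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           strip.white = TRUE)
  if (ncol(tab) < 2) stop("founder table needs a marker column plus at least ",
                          "one founder column")
  markers <- tab[[1]]
  if (anyDuplicated(markers))
    stop("duplicate marker name(s): ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  ids <- colnames(tab)[-1]
  panel <- marker_panel(markers)
  alleles <- lapply(ids, function(f) {
    cells <- tab[[f]]
    lapply(seq_along(cells), function(i) {
      a <- parse_allele_cell(cells[i])
      if (length(a) == 0L || anyNA(a))
        stop("cannot parse allele cell '", cells[i], "' (marker ", markers[i],
             ", founder ", f, ", line ", i + 1, ")")
      a
    })
  })
  names(alleles) <- ids
  list(panel = panel, founders = founder_set(panel, alleles))
}

# split a cell on comma / en-dash (U+2212, U+2013) / hyphen / whitespace,
# dropping parentheses used to mark minor variants
parse_allele_cell <- function(cell) {
  cell <- gsub("[()]", " ", cell)
  parts <- strsplit(cell, "[,−–—[:space:]-]+", perl = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  suppressWarnings(as.integer(parts))
}

#' Write a founder-haplotype table
#'
#' Inverse of [read_founder_table()]; multi-allele cells are comma-joined.
#'
#' @param founders a [founder_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_founder_table <- function(founders, path) {
  stopifnot(inherits(founders, "founder_set"))
  cols <- lapply(founders$founders, function(f)
    vapply(founders$alleles[[f]], paste, character(1), collapse = ","))
  tab <- data.frame(marker = founders$panel$markers, cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("marker", founders$founders)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased-haplotype table
#'
#' TSV with a haplotype id in the first column and one integer allele column
#' per marker; "NA" marks missing alleles. Columns are matched to the panel
#' by header name, not position.
#'
#' @param path path to the TSV file.
#' @param panel a [marker_panel()] the haplotypes must cover.
#' @return Integer matrix (haplotypes x markers) with ids as row names,
#'   columns in panel order.
#' @export
read_haplotype_table <- function(path, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  tab <- read_aligned_table(path, panel$markers)
  mat <- as.matrix(tab[-1])
  storage.mode(mat) <- "integer"
  rownames(mat) <- tab[[1]]
  mat[, panel$markers, drop = FALSE]
}

#' Write a phased-haplotype table
#'
#' @param haps integer matrix (haplotypes x markers), marker names as
#'   column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(haps, path) {
  ids <- rownames(haps)
  if (is.null(ids)) ids <- sprintf("hap%04d", seq_len(nrow(haps)))
  tab <- data.frame(haplotype = ids, haps, check.names = FALSE,
                    row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype table
#'
#' Genotypes are stored as two integer columns per marker, named
#' `<marker>_1` and `<marker>_2` (unordered allele pair; "NA" for missing),
#' with the sample id in the first column. Columns are matched by name.
#'
#' @param path path to the TSV file.
#' @param panel a [marker_panel()].
#' @return data.frame with `sample` plus the two allele columns per marker,
#'   in panel order.
#' @export
read_genotype_table <- function(path, panel) {
  stopifnot(inherits(panel, "marker_panel"))
  wanted <- as.vector(rbind(paste0(panel$markers, "_1"),
                            paste0(panel$markers, "_2")))
  tab <- read_aligned_table(path, wanted)
  out <- tab[c(colnames(tab)[1], wanted)]
  colnames(out)[1] <- "sample"
  for (w in wanted) out[[w]] <- as.integer(out[[w]])
  out
}

#' @rdname read_genotype_table
#' @param genotypes data.frame as produced by [simulate_population()].
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# shared reader: header-aligned TSV, id in first column, required columns
read_aligned_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, na.strings = "NA")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(colnames(tab)[-1], required)
  if (length(extra))
    stop("unknown marker column(s): ", paste(extra, collapse = ", "))
  tab
}

#' Read a recombination-count spectrum
#'
#' TSV with columns `k` (0, 1, 2, ...) and `n_k`.
#'
#' @param path path to the TSV file.
#' @return A [recomb_spectrum()].
#' @examples
#' read_spectrum_table(system.file("extdata",
#'   "mauritian_mhc_spectrum.tsv", package = "mhcrec"))
#' @export
read_spectrum_table <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#")
  if (!all(c("k", "n_k") %in% colnames(tab)))
    stop("spectrum file needs columns 'k' and 'n_k'")
  tab <- tab[order(tab$k), ]
  if (!identical(as.integer(tab$k), seq_len(nrow(tab)) - 1L))
    stop("'k' must run 0, 1, 2, ... without gaps")
  recomb_spectrum(tab$n_k)
}

#' Run the full estimation pipeline
#'
#' Classify (or load) the spectrum, fit the Poisson intensity and its
#' confidence interval, test the goodness of fit, convert to per-generation
#' rates with the homozygosity correction, and summarise the harmonic-mean
#' Ne over a demographic grid. Each stage logs its headline numbers via
#' `message()`.
#'
#' @param spectrum a [recomb_spectrum()], counts vector, or `NULL` if
#'   `haplotypes` is given.
#' @param haplotypes optional phased haplotype matrix to classify (requires
#'   `founders`).
#' @param founders optional list as returned by [read_founder_table()].
#' @param alpha risk level for the confidence interval.
#' @param min_expected chi-squared bin-merging threshold.
#' @param elapsed_years years since the founding event.
#' @param generation_times generation times (years) to report rates for.
#' @param het_freq heterozygote frequency for the correction.
#' @param ne_grid_spec list with vectors `N0`, `r0`, `T` and scalar `K` for
#'   the Ne grid, or `NULL` to skip it.
#' @param orphan_policy passed to [classify_population()].
#' @return Object of class `mhcrec_report` (see [report_to_json()]).
#' @examples
#' rep <- run_pipeline(spectrum = c(1030, 382, 74, 14))
#' rep$fit$lambda_hat
#' @export
run_pipeline <- function(spectrum = NULL, haplotypes = NULL, founders = NULL,
                         alpha = 0.05, min_expected = 5,
                         elapsed_years = 400, generation_times = c(4, 8),
                         het_freq = 0.90,
                         ne_grid_spec = list(N0 = c(12, 90),
                                             r0 = c(0.1, 0.4),
                                             K = 12000, T = c(50, 100)),
                         orphan_policy = "mutation") {
  if (is.null(spectrum)) {
    if (is.null(haplotypes) || is.null(founders))
      stop("either a spectrum or haplotypes plus founders must be supplied")
    message("classify: ", nrow(haplotypes), " haplotypes over ",
            length(founders$panel$markers), " markers")
    spectrum <- classify_population(founders$panel, founders$founders,
                                    haplotypes, orphan_policy = orphan_policy)
  }
  sp <- as_spectrum(spectrum)
  message("spectrum: n = ", sp$n, "; counts = ",
          paste(sp$counts, collapse = ", "))
  fit <- poisson_fit(sp, alpha = alpha)
  message(sprintf("fit: lambda_hat = %.4f, %d%% CI [%.4f, %.4f]",
                  fit$lambda_hat, round(100 * (1 - alpha)),
                  fit$ci_low, fit$ci_high))
  gof <- tryCatch(gof_test(sp, min_expected = min_expected),
                  error = function(e) {
                    message("gof: not computable (", conditionMessage(e), ")")
                    NULL
                  })
  if (!is.null(gof))
    message(sprintf("gof: chi-squared = %.3f, df = %d, p = %.3f",
                    gof$statistic, gof$df, gof$p_value))
  rates <- estimate_rates(fit, elapsed_years = elapsed_years,
                          generation_times = generation_times,
                          het_freq = het_freq)
  message("rates/generation: ",
          paste(sprintf("%.4f (gen time %g y)", rates$rate,
                        rates$generation_time), collapse = "; "))
  grid <- NULL
  if (!is.null(ne_grid_spec)) {
    grid <- ne_grid(ne_grid_spec$N0, ne_grid_spec$r0, ne_grid_spec$K,
                    ne_grid_spec$T)
    message(sprintf("Ne grid: harmonic-mean Ne in [%.0f, %.0f]",
                    attr(grid, "range")[1], attr(grid, "range")[2]))
  }
  structure(list(
    spectrum = list(k = sp$k, counts = sp$counts, n = sp$n, types = sp$types),
    fit = list(lambda_hat = fit$lambda_hat, ci_low = fit$ci_low,
               ci_high = fit$ci_high, alpha = alpha, n = fit$n),
    gof = if (!is.null(gof))
      list(statistic = gof$statistic, df = gof$df, p_value = gof$p_value,
           bins = gof$merged_bins),
    rates = rates,
    ne_grid = grid,
    ne_range = if (!is.null(grid)) attr(grid, "range") else NULL,
    settings = list(alpha = alpha, min_expected = min_expected,
                    elapsed_years = elapsed_years,
                    generation_times = generation_times,
                    het_freq = het_freq, orphan_policy = orphan_policy),
    version = as.character(utils::packageVersion("mhcrec"))),
    class = "mhcrec_report")
}

#' @export
print.mhcrec_report <- function(x, ...) {
  cat("=== recombination-rate report ===\n")
  cat("spectrum n =", x$spectrum$n, "; counts:",
      paste(x$spectrum$counts, collapse = ", "), "\n")
  cat(sprintf("lambda_hat = %.3f, CI [%.3f, %.3f]\n",
              x$fit$lambda_hat, x$fit$ci_low, x$fit$ci_high))
  if (!is.null(x$gof))
    cat(sprintf("gof chi-squared = %.3f (df %d, p = %.3f)\n",
                x$gof$statistic, x$gof$df, x$gof$p_value))
  else cat("gof: not computable (spectrum too coarse)\n")
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf(
      "rate/generation (gen time %g y): %.4f detectable, %.4f corrected\n",
      x$rates$generation_time[i], x$rates$rate[i], x$rates$rate_corrected[i]))
  if (!is.null(x$ne_range))
    cat(sprintf("harmonic-mean Ne range: %.0f-%.0f\n",
                x$ne_range[1], x$ne_range[2]))
  invisible(x)
}

#' Serialise / deserialise a pipeline report as JSON
#'
#' Values are written at full precision, with a `display` block rounded for
#' reading (intensities and rates to 3-4 significant figures, expected counts
#' to 2 decimals).
#'
#' @param report an `mhcrec_report` from [run_pipeline()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return `report_to_json()`: the path (invisibly) or the JSON string;
#'   `report_from_json()`: the report list.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mhcrec_report"))
  out <- unclass(report)
  out$display <- list(
    lambda_hat = round(report$fit$lambda_hat, 3),
    ci = round(c(report$fit$ci_low, report$fit$ci_high), 3),
    chi_squared = if (!is.null(report$gof)) round(report$gof$statistic, 3),
    p_value = if (!is.null(report$gof)) round(report$gof$p_value, 3),
    expected = if (!is.null(report$gof)) round(report$gof$bins$expected, 2),
    rates = round(report$rates$rate, 4),
    rates_corrected = round(report$rates$rate_corrected, 4))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$rates <- as.data.frame(x$rates)
  if (!is.null(x$gof)) x$gof$bins <- as.data.frame(x$gof$bins)
  if (!is.null(x$ne_grid)) x$ne_grid <- as.data.frame(x$ne_grid)
  class(x) <- "mhcrec_report"
  x
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file mirroring the arguments of [run_pipeline()] and
#' [sim_config()]; used by the command-line interface, where flags override
#' file values.
#'
#' @param path path to the YAML file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
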