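#' Configuration of the forward-time founder-expansion simulation
#'
#' Describes a diploid population founded by a handful of animals carrying
#' known haplotypes, expanding along a Verhulst logistic trajectory with
#' random mating, non-overlapping generations, per-meiosis recombination and
#' rare stepwise microsatellite mutation. Defaults reflect the Mauritian
#' macaque scenario: 12 founders carrying 7 haplotypes, K = 12000, 100
#' generations.
#'
#' @param founders a [founder_set()] providing the founding haplotypes
#'   (represented by their canonical allele at multi-allele markers).
#' @param growth a [verhulst_params()]; N0 is the founder census.
#' @param generations number of generations T simulated after founding.
#' @param c per-meiosis recombination probability across the region. Under
#'   the default `"bernoulli"` model each gamete performs at most one
#'   crossover (adequate for c of order 0.01 or below); `"poisson"` draws a
#'   Poisson(c) number of crossovers for stress testing.
#' @param mu per-marker, per-meiosis mutation probability; a mutation shifts
#'   the allele by one repeat unit up or down.
#' @param sample_size number of animals sampled (without replacement) from
#'   the final generation.
#' @param founder_freqs optional named frequencies of the founding
#'   haplotypes among the 2 * N0 founder haplotype copies; default
#'   near-equal. True founding frequencies are generally unknown.
#' @param repeat_unit repeat-unit length in bp for the mutation step
#'   (default 2).
#' @param crossover_model `"bernoulli"` or `"poisson"` (see `c`).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(founders,
                       growth = verhulst_params(12, 12000, 0.4),
                       generations = 100,
                       c = 0.004,
                       mu = 0,
                       sample_size = 750,
                       founder_freqs = NULL,
                       repeat_unit = 2L,
                       crossover_model = c("bernoulli", "poisson")) {
  stopifnot(inherits(founders, "founder_set"),
            inherits(growth, "verhulst_params"))
  crossover_model <- match.arg(crossover_model)
  if (c < 0 || c > 1 || mu < 0 || mu > 1)
    stop("'c' and 'mu' must be probabilities in [0, 1]")
  if (generations < 1) stop("'generations' must be at least 1")
  if (sample_size < 1) stop("'sample_size' must be at least 1")
  if (round(growth$N0) < 2)
    stop("the founder census must hold at least 2 animals")
  if (!is.null(founder_freqs)) {
    if (is.null(names(founder_freqs)) ||
        !setequal(names(founder_freqs), founders$founders))
      stop("'founder_freqs' must be named by the founder ids")
    if (any(founder_freqs < 0) || sum(founder_freqs) <= 0)
      stop("'founder_freqs' must be non-negative with positive total")
    founder_freqs <- founder_freqs[founders$founders] / sum(founder_freqs)
  }
  structure(list(founders = founders, growth = growth,
                 generations = as.integer(generations), c = c, mu = mu,
                 sample_size = as.integer(sample_size),
                 founder_freqs = founder_freqs,
                 repeat_unit = as.integer(repeat_unit),
                 crossover_model = crossover_model),
            class = "sim_config")
}

# number of set bits among the low `nbits` bits of each integer
popcount <- function(x, nbits) {
  out <- integer(length(x))
  for (b in seq_len(nbits) - 1L)
    out <- out + as.integer(bitwAnd(x, bitwShiftL(1L, b)) != 0L)
  out
}

# integer founder-copy counts for 2*N0 haplotype copies (largest remainder)
founder_copy_counts <- function(freqs, total) {
  raw <- freqs * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a founder bottleneck followed by logistic expansion
#'
#' Forward-time diploid simulation. Each generation t has census
#' round(N_t) under the Verhulst trajectory; every offspring draws two
#' distinct parents uniformly at random; each gamete copies one parental
#' haplotype and, with probability c, performs a crossover at a uniformly
#' chosen inter-marker interval, switching to the homologous haplotype.
#'
#' Each haplotype carries the set of crossover junctions present in its
#' material (one bit per inter-marker interval): a crossover adds a junction,
#' and inherited junctions survive exactly when the segment containing them
#' is transmitted. The true recombination count of a sampled haplotype is
#' the number of such junctions — the ground truth against which the
#' parsimony classifier is a lower bound, since crossovers between identical
#' or allele-sharing haplotypes create junctions the classifier cannot see.
#' An event whose junction is excised by a later crossover, or never
#' transmitted, leaves no trace in the sample and is not counted. Mutation
#' perturbs single alleles by one repeat unit (with mutation enabled, a
#' mutant allele can coincidentally match another founder and mimic a
#' switch, so the lower-bound guarantee holds strictly only at mu = 0).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; a fixed seed makes the result bit-identical
#'   across runs.
#' @param track_origin keep the per-marker founder-of-origin matrix (the
#'   true mosaic). Disable to save time/memory in large batch runs.
#' @return Object of class `sim_result`:
#' \describe{
#'   \item{haplotypes}{integer matrix (2 x sample_size rows, markers as
#'     columns); rows 2i-1, 2i belong to animal i.}
#'   \item{genotypes}{data.frame of unordered allele pairs per marker
#'     (columns `<marker>_1`, `<marker>_2`).}
#'   \item{true_counts}{number of crossover junctions carried by each
#'     sampled haplotype (>= the parsimony count when mu = 0).}
#'   \item{true_origin}{founder-of-origin matrix (founder index per marker),
#'     or NULL.}
#'   \item{census}{realised census sizes for generations 0..T.}
#' }
#' @export
simulate_population <- function(config, seed, track_origin = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  fs <- config$founders
  panel <- fs$panel
  M <- length(panel$markers)
  nf <- length(fs$founders)
  fmat <- t(vapply(fs$founders, function(id) founder_haplotype(fs, id),
                   integer(M)))  # founders x markers

  if (M - 1L > 30L)
    stop("junction tracking supports at most 31 markers")
  n0 <- as.integer(round(verhulst_size(config$growth, 0)))
  freqs <- config$founder_freqs
  if (is.null(freqs))
    freqs <- stats::setNames(rep(1 / nf, nf), fs$founders)
  copies <- founder_copy_counts(freqs, 2L * n0)
  fidx <- sample(rep.int(seq_len(nf), copies))  # shuffle copies onto animals

  haps <- fmat[fidx, , drop = FALSE]
  origin <- if (track_origin)
    matrix(fidx, nrow = 2L * n0, ncol = M) else NULL
  masks <- integer(2L * n0)  # bit j-1 set <=> junction in interval j

  T <- config$generations
  census <- integer(T + 1L)
  census[1L] <- n0
  for (t in seq_len(T)) {
    n_prev <- census[t]
    n_off <- max(2L, as.integer(round(verhulst_size(config$growth, t))))
    census[t + 1L] <- n_off
    p1 <- sample.int(n_prev, n_off, replace = TRUE)
    p2 <- sample.int(n_prev - 1L, n_off, replace = TRUE)
    p2 <- p2 + (p2 >= p1)             # uniform over parents distinct from p1
    pv <- as.vector(rbind(p1, p2))    # gamete 2i-1 from p1[i], 2i from p2[i]
    G <- 2L * n_off
    s <- sample.int(2L, G, replace = TRUE) - 1L
    srow <- 2L * pv - 1L + s
    orow <- 2L * pv - 1L + (1L - s)

    nc <- if (config$crossover_model == "bernoulli")
      stats::rbinom(G, 1L, config$c) else stats::rpois(G, config$c)
    bp <- integer(G)
    one <- nc == 1L
    if (any(one)) bp[one] <- sample.int(M - 1L, sum(one), replace = TRUE)

    new_haps <- haps[srow, , drop = FALSE]
    other_haps <- haps[orow, , drop = FALSE]
    # markers beyond the breakpoint interval come from the homologous hap
    take_other <- one & col(new_haps) > bp
    new_haps[take_other] <- other_haps[take_other]
    if (track_origin) {
      new_origin <- origin[srow, , drop = FALSE]
      other_origin <- origin[orow, , drop = FALSE]
      new_origin[take_other] <- other_origin[take_other]
    }
    # junction masks: keep the start hap's junctions left of the breakpoint,
    # the homologue's junctions right of it, and add the new one at bp
    new_masks <- masks[srow]
    if (any(one)) {
      i1 <- which(one)
      b <- bp[i1]
      low <- bitwShiftL(1L, b - 1L) - 1L
      high <- bitwNot(bitwShiftL(1L, b) - 1L)
      new_masks[i1] <- bitwOr(bitwOr(bitwAnd(masks[srow[i1]], low),
                                     bitwAnd(masks[orow[i1]], high)),
                              bitwShiftL(1L, b - 1L))
    }
    multi <- which(nc >= 2L)
    for (g in multi) {
      cur <- haps[srow[g], ]; alt <- haps[orow[g], ]
      curm <- masks[srow[g]]; altm <- masks[orow[g]]
      if (track_origin) { curo <- origin[srow[g], ]; alto <- origin[orow[g], ] }
      for (b in sort(sample.int(M - 1L, nc[g], replace = TRUE))) {
        idx <- (b + 1L):M
        tmp <- cur[idx]; cur[idx] <- alt[idx]; alt[idx] <- tmp
        low <- bitwShiftL(1L, b - 1L) - 1L
        high <- bitwNot(bitwShiftL(1L, b) - 1L)
        bit <- bitwShiftL(1L, b - 1L)
        cm2 <- bitwOr(bitwOr(bitwAnd(curm, low), bitwAnd(altm, high)), bit)
        am2 <- bitwOr(bitwOr(bitwAnd(altm, low), bitwAnd(curm, high)), bit)
        curm <- cm2; altm <- am2
        if (track_origin) {
          tmpo <- curo[idx]; curo[idx] <- alto[idx]; alto[idx] <- tmpo
        }
      }
      new_haps[g, ] <- cur
      new_masks[g] <- curm
      if (track_origin) new_origin[g, ] <- curo
    }

    if (config$mu > 0) {
      mut <- matrix(stats::runif(G * M) < config$mu, G, M)
      nmut <- sum(mut)
      if (nmut > 0) {
        step <- sample(c(-1L, 1L), nmut, replace = TRUE) * config$repeat_unit
        new_haps[mut] <- pmax(new_haps[mut] + step, 1L)
      }
    }

    haps <- new_haps
    masks <- new_masks
    if (track_origin) origin <- new_origin
  }

  final_n <- census[T + 1L]
  if (config$sample_size > final_n)
    stop("sample size ", config$sample_size,
         " exceeds the final census of ", final_n, " animals")
  animals <- sort(sample.int(final_n, config$sample_size))
  rows <- as.vector(rbind(2L * animals - 1L, 2L * animals))
  haps <- haps[rows, , drop = FALSE]
  colnames(haps) <- panel$markers
  counts <- popcount(masks[rows], M - 1L)
  origin <- if (track_origin) {
    o <- origin[rows, , drop = FALSE]
    colnames(o) <- panel$markers
    o
  } else NULL

  ids <- sprintf("animal%04d", seq_len(config$sample_size))
  geno <- data.frame(sample = ids, stringsAsFactors = FALSE)
  for (m in seq_len(M)) {
    a1 <- haps[seq(1L, nrow(haps), 2L), m]
    a2 <- haps[seq(2L, nrow(haps), 2L), m]
    geno[[paste0(panel$markers[m], "_1")]] <- pmin(a1, a2)
    geno[[paste0(panel$markers[m], "_2")]] <- pmax(a1, a2)
  }

  structure(list(haplotypes = haps, genotypes = geno, true_counts = counts,
                 true_origin = origin, census = census, config = config,
                 seed = as.integer(seed)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Forward simulation: %d generations, final census %d, %d animals sampled\n",
    x$config$generations, x$census[length(x$census)], x$config$sample_size))
  cat(sprintf("  mean true recombination count per haplotype: %.3f\n",
              mean(x$true_counts)))
  invisible(x)
}

#' Parameter-recovery experiment for the Poisson estimator
#'
#' Repeatedly simulates the founding/expansion scenario at a known
#' per-generation recombination probability c, classifies the sampled
#' haplotypes by founder-mosaic parsimony, fits the Poisson intensity and
#' compares lambda_hat / T against c. Because crossovers in founder-
#' homozygous backgrounds leave no detectable mosaic, parsimony counts are a
#' lower bound on the truth; the undercount fraction is reported alongside.
#'
#' @param config a [sim_config()].
#' @param replicates number of independent replicates.
#' @param seed root seed; replicate r uses seed + r - 1.
#' @param orphan_policy passed to [classify_population()].
#' @return data.frame with one row per replicate: `c_true`, `lambda_hat`,
#'   `rate_per_gen` (lambda_hat / T), `het_freq` (observed fraction of
#'   animals carrying two distinct haplotypes), `rate_corrected`
#'   (rate_per_gen / het_freq, the full pipeline including the
#'   homozygosity correction), `true_mean` (mean true count), `undercount`
#'   (fraction of true events invisible to parsimony) and `ci_covers`
#'   (whether the CI for the intensity covers the detectable expectation,
#'   i.e. the true mean count).
#' @export
recovery_experiment <- function(config, replicates, seed = 1,
                                orphan_policy = "mutation") {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  T <- config$generations
  panel <- config$founders$panel
  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_population(config, seed = seed + r - 1L,
                               track_origin = FALSE)
    sp <- classify_population(panel, config$founders, sim$haplotypes,
                              orphan_policy = orphan_policy)
    fit <- poisson_fit(sp)
    parsimony_total <- sum(sp$k * sp$counts)
    true_total <- sum(sim$true_counts)
    keys <- apply(sim$haplotypes, 1, paste, collapse = ",")
    odd <- seq(1L, length(keys), 2L)
    het <- mean(keys[odd] != keys[odd + 1L])
    res[[r]] <- data.frame(
      replicate = r,
      c_true = config$c,
      lambda_hat = fit$lambda_hat,
      rate_per_gen = fit$lambda_hat / T,
      het_freq = het,
      rate_corrected = if (het > 0) fit$lambda_hat / T / het else NA_real_,
      true_mean = mean(sim$true_counts),
      undercount = if (true_total > 0)
        1 - parsimony_total / true_total else NA_real_,
      ci_covers = fit$ci_low <= mean(sim$true_counts) &&
        mean(sim$true_counts) <= fit$ci_high)
  }
  do.call(rbind, res)
}
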