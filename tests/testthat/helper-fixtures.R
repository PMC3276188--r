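# shared fixtures and independent oracles

mhc_fixture <- function() {
  read_founder_table(system.file("extdata", "mauritian_mhc_founders.tsv",
                                 package = "mhcrec"))
}

mhc_spectrum <- function() c(1030, 382, 74, 14)

# Independent brute-force oracle for the minimum-switch mosaic: enumerate
# every founder sequence over the markers, keep the compatible ones
# (orphan rows wildcarded), and count founder changes directly.
brute_min_switches <- function(cm) {
  m <- nrow(cm)
  f <- ncol(cm)
  cm[rowSums(cm) == 0L, ] <- TRUE
  seqs <- as.matrix(expand.grid(rep(list(seq_len(f)), m),
                                KEEP.OUT.ATTRS = FALSE))
  ok <- rep(TRUE, nrow(seqs))
  for (i in seq_len(m)) ok <- ok & cm[i, seqs[, i]]
  seqs <- seqs[ok, , drop = FALSE]
  stopifnot(nrow(seqs) > 0)
  if (m == 1L) return(0L)
  min(rowSums(seqs[, -1, drop = FALSE] != seqs[, -m, drop = FALSE]))
}

# random small panel/founder-set instances with heavy allele sharing so that
# ambiguous mosaics and orphans both occur
random_instance <- function(n_markers, n_founders, n_alleles = 3,
                            p_orphan = 0.1, p_missing = 0.1) {
  panel <- marker_panel(paste0("M", seq_len(n_markers)))
  alleles <- lapply(seq_len(n_founders), function(f)
    lapply(seq_len(n_markers), function(m)
      sample(100 + 2 * seq_len(n_alleles), 1)))
  names(alleles) <- paste0("F", seq_len(n_founders))
  fs <- founder_set(panel, alleles)
  hap <- vapply(seq_len(n_markers), function(m) {
    if (runif(1) < p_missing) return(NA_integer_)
    if (runif(1) < p_orphan) return(999L)  # matches no founder
    f <- sample(n_founders, 1)
    fs$alleles[[f]][[m]][1]
  }, integer(1))
  list(panel = panel, founders = fs, hap = hap)
}
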