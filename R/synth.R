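#' @importFrom stats rpois rgeom
NULL

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' Generating truth for a synthetic SFS dataset
#'
#' Bundles every parameter needed to simulate (and exactly regenerate, via
#' the seed) an observed neutral + focal insertion/deletion SFS dataset.
#' Defaults reproduce the study conditions this package targets: samples of
#' 10 diploid individuals (n = 20 chromosomes), neutral mutation rates at
#' the ancestral-repeat diversity level, a deleterious gamma DFE for focal
#' noncoding sites with the published maximum-likelihood parameters
#' (insertions: theta 1.7e-4, shape 0.0345, scale 1553; deletions: theta
#' 2.93e-4, shape 0.106, scale 715), and polarization errors of 0.011
#' (insertions) and 0.0166 (deletions).
#'
#' @param n haploid sample size.
#' @param theta_neutral per-type neutral per-site rates `c(ins=, del=)`.
#' @param focal per-type focal model: a list with either
#'   `list(gammas =, thetas =)` (discrete classes) or
#'   `list(shape =, scale =, theta =)` (gamma DFE) per type.
#' @param L_neutral,L_focal callable sites per region (same for both
#'   types).
#' @param eps [orientation_errors()].
#' @param r demography multipliers (length `n - 1`, `r[1] = 1`) or `NULL`.
#' @param seed integer seed.
#' @return Object of class `"synth_truth"` (fully serializable list).
#' @export
synth_sfs_truth <- function(
    n = 20L,
    theta_neutral = c(ins = 1.2e-4, del = 1.75e-4),
    focal = list(
      ins = list(shape = 0.0345, scale = 1553, theta = 1.7e-4),
      del = list(shape = 0.106, scale = 715, theta = 2.93e-4)),
    L_neutral = 1e6, L_focal = 1e6,
    eps = orientation_errors(0.011, 0.0166),
    r = NULL, seed = 1L) {
  structure(list(n = as.integer(n), theta_neutral = theta_neutral,
                 focal = focal, L_neutral = L_neutral, L_focal = L_focal,
                 eps = eps, r = r, seed = as.integer(seed)),
            class = "synth_truth")
}

# expected observed-scale spectra implied by a synth_truth
expected_from_truth <- function(truth, K = 100L, nodes = 128L) {
  n <- truth$n
  en_ins <- expected_sfs_discrete(0, truth$theta_neutral[["ins"]],
                                  truth$L_neutral, n, truth$r, nodes)
  en_del <- expected_sfs_discrete(0, truth$theta_neutral[["del"]],
                                  truth$L_neutral, n, truth$r, nodes)
  focal_one <- function(fc) {
    if (!is.null(fc$gammas)) {
      e <- numeric(n - 1L)
      for (j in seq_along(fc$gammas))
        e <- e + expected_sfs_discrete(fc$gammas[j], fc$thetas[j],
                                       truth$L_focal, n, truth$r, nodes)
      e
    } else {
      expected_sfs_gamma(fc$shape, fc$scale, fc$theta, truth$L_focal, n,
                         truth$r, K, nodes)
    }
  }
  list(neutral = fold_in_errors(en_ins, en_del, truth$eps),
       focal = fold_in_errors(focal_one(truth$focal$ins),
                              focal_one(truth$focal$del), truth$eps))
}

#' Simulate an observed SFS dataset from known truth
#'
#' Builds the model's expected spectra (neutral reference at gamma = 0,
#' focal region under the truth's DFE), applies the demography multipliers
#' and the forward misorientation mixing, then draws every frequency-class
#' count as an independent Poisson variable. Identical seeds give
#' identical datasets.
#'
#' @param truth a [synth_sfs_truth()].
#' @return A [dfe_data()] of observed integer spectra, with the truth
#'   attached as attribute `"truth"`.
#' @export
simulate_sfs_dataset <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  e <- expected_from_truth(truth)
  n <- truth$n
  d <- with_seed(truth$seed, {
    list(ni = rpois(n - 1L, e$neutral$ins), nd = rpois(n - 1L, e$neutral$del),
         fi = rpois(n - 1L, e$focal$ins), fd = rpois(n - 1L, e$focal$del))
  })
  out <- dfe_data(
    sfs_pair(sfs(d$ni, n, truth$L_neutral), sfs(d$nd, n, truth$L_neutral)),
    sfs_pair(sfs(d$fi, n, truth$L_focal), sfs(d$fd, n, truth$L_focal)))
  attr(out, "truth") <- truth
  out
}

#' Generating truth for a toy genome
#'
#' Defines a genome of `n_chrom` chromosomes, regularly spaced exons, a
#' distance-dependent mutation-rate profile
#' `theta(d) = theta_max * (1 - exp(-d / tau))` (or flat when
#' `tau = 0`), per-chromosome cubic genetic maps, and polarization error
#' rates used to corrupt outgroup alleles.
#'
#' @param n_chrom,chrom_len genome layout (default 10 x 5 Mb).
#' @param exon_spacing,exon_len mean exon spacing and exon length (bp).
#' @param theta_max per-type asymptotic rates `c(ins=, del=)`.
#' @param tau distance scale (bp) of diversity recovery away from exons;
#'   `0` means flat `theta(d) = theta_max`.
#' @param n haploid sample size.
#' @param eps [orientation_errors()] used to flip outgroup alleles.
#' @param map_coef function(chrom index) -> cubic coefficients
#'   `c(c0, c1, c2, c3)` of cM on bp, or `NULL` for built-in defaults
#'   (linear terms varying 2-10 cM/Mb across chromosomes plus a small
#'   cubic bend).
#' @param seed integer seed.
#' @return Object of class `"synth_genome_truth"`.
#' @export
synth_genome_truth <- function(n_chrom = 10L, chrom_len = 5e6,
                               exon_spacing = 25000L, exon_len = 200L,
                               theta_max = c(ins = 1.7e-4, del = 2.93e-4),
                               tau = 25000, n = 20L,
                               eps = orientation_errors(0.011, 0.0166),
                               map_coef = NULL, seed = 1L) {
  if (is.null(map_coef)) {
    map_coef <- function(k) {
      base <- (2 + 8 * (k - 1) / max(n_chrom - 1, 1)) * 1e-6 # cM per bp
      c(0, base, 0, 2e-21)
    }
  }
  structure(list(n_chrom = as.integer(n_chrom), chrom_len = chrom_len,
                 exon_spacing = as.integer(exon_spacing),
                 exon_len = as.integer(exon_len),
                 theta_max = theta_max, tau = tau, n = as.integer(n),
                 eps = eps, map_coef = map_coef, seed = as.integer(seed)),
            class = "synth_genome_truth")
}

theta_at_distance <- function(truth, d) {
  f <- if (truth$tau > 0) 1 - exp(-d / truth$tau) else 1
  list(ins = truth$theta_max[["ins"]] * f,
       del = truth$theta_max[["del"]] * f)
}

#' Simulate a toy genome with known truth
#'
#' Places exons at regular spacing along each chromosome, then drops
#' variants by a Poisson process whose per-site intensity is
#' `theta(d) * a1(n)` (the expected segregating-site density under the
#' neutral SFS shape), where `d` is the distance to the nearest exon edge.
#' Derived-allele counts are drawn from the normalized neutral shape
#' (proportional to `1/i`); insertion/deletion type follows the theta
#' ratio; INDEL lengths follow a geometric law with ~80% shorter than
#' 5 bp. Both outgroup alleles equal the true ancestral allele, flipped
#' together to the derived allele with the per-type polarization-error
#' probability. The genetic map is the truth's cubic per chromosome,
#' tabulated every 250 kb.
#'
#' @param truth a [synth_genome_truth()].
#' @return List of class `"synth_genome"` with `variants` (data.table
#'   including the true ancestral state and an `outgroups` matrix),
#'   `exons`, `callable` (noncoding complement), `map_points`,
#'   `chrom_lengths`, and `truth`.
#' @export
simulate_genome <- function(truth) {
  stopifnot(inherits(truth, "synth_genome_truth"))
  with_seed(truth$seed, simulate_genome_impl(truth))
}

simulate_genome_impl <- function(truth) {
  n <- truth$n
  a1 <- sum(1 / seq_len(n - 1L))
  sfs_shape <- (1 / seq_len(n - 1L)) / a1
  chroms <- paste0("chr", seq_len(truth$n_chrom))
  chrom_lengths <- stats::setNames(rep(truth$chrom_len, truth$n_chrom), chroms)
  exon_rows <- list(); var_rows <- list(); map_rows <- list(); call_rows <- list()
  # geometric length law: P(len <= 4) ~ 0.8
  len_p <- 1 - 0.2^(1 / 4)
  for (k in seq_len(truth$n_chrom)) {
    ch <- chroms[k]
    len <- truth$chrom_len
    ex_start <- seq(truth$exon_spacing, len - truth$exon_len,
                    by = truth$exon_spacing)
    ex <- data.table::data.table(chrom = ch, start = as.integer(ex_start),
                                 end = as.integer(ex_start + truth$exon_len - 1L))
    exon_rows[[k]] <- ex
    ir_ex <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    ir_all <- IRanges::IRanges(1L, as.integer(len))
    ir_nc <- IRanges::setdiff(ir_all, ir_ex)
    call_rows[[k]] <- data.table::data.table(
      chrom = ch, start = IRanges::start(ir_nc), end = IRanges::end(ir_nc))
    # 1-kb resolution distance strata out to 100 kb, then a far stratum
    strata <- distance_bin_ranges(ir_ex, len, 1000L, 100L)
    far <- ir_nc
    for (s in strata) far <- IRanges::setdiff(far, s)
    strata <- c(strata, list(far))
    d_mid <- c(1000 * (seq_len(100) - 0.5), 150000)
    for (si in seq_along(strata)) {
      w <- sum(IRanges::width(strata[[si]]))
      if (w == 0) next
      th <- theta_at_distance(truth, d_mid[si])
      n_ins <- rpois(1, th$ins * a1 * w)
      n_del <- rpois(1, th$del * a1 * w)
      n_tot <- n_ins + n_del
      if (n_tot == 0) next
      # uniform positions within the interval set
      ws <- IRanges::width(strata[[si]])
      iv <- sample.int(length(ws), n_tot, replace = TRUE, prob = ws)
      pos <- IRanges::start(strata[[si]])[iv] +
        floor(runif(n_tot) * ws[iv])
      vtype <- c(rep("insertion", n_ins), rep("deletion", n_del))
      dc <- sample.int(n - 1L, n_tot, replace = TRUE, prob = sfs_shape)
      ilen <- stats::rgeom(n_tot, len_p) + 1L
      ilen <- pmin(ilen, 50L)
      var_rows[[length(var_rows) + 1L]] <- data.table::data.table(
        chrom = ch, pos = as.integer(pos), vtype = vtype,
        derived_count = dc, length = ilen)
    }
    cf <- truth$map_coef(k)
    mp <- seq(0, len, by = 250000)
    map_rows[[k]] <- data.table::data.table(
      chrom = ch, pos_bp = mp,
      cM = cf[1] + cf[2] * mp + cf[3] * mp^2 + cf[4] * mp^3)
  }
  variants <- data.table::rbindlist(var_rows)
  data.table::setorderv(variants, c("chrom", "pos"))
  # drop duplicate positions (Poisson process collisions)
  variants <- unique(variants, by = c("chrom", "pos"))
  m <- nrow(variants)
  # allele construction: anchor base + tract; ancestral is the shorter
  # allele for insertions, the longer for deletions
  tract <- vapply(variants$length, function(l)
    paste(rep("T", l), collapse = ""), character(1))
  is_ins <- variants$vtype == "insertion"
  # in half the records the REF allele carries the derived state
  ref_is_anc <- runif(m) < 0.5
  short_a <- "A"
  long_a <- paste0("A", tract)
  anc <- ifelse(is_ins, short_a, long_a)
  der <- ifelse(is_ins, long_a, short_a)
  variants$ref <- ifelse(ref_is_anc, anc, der)
  variants$alt <- ifelse(ref_is_anc, der, anc)
  variants$ancestral_true <- anc
  # derived allele count in VCF terms: ALT copies
  variants$alt_count <- ifelse(ref_is_anc, variants$derived_count,
                               truth$n - variants$derived_count)
  # outgroups carry the true ancestral allele; with probability eps (per
  # type) both are flipped to the derived allele -> misorientation
  flip_p <- ifelse(is_ins, truth$eps$eps_ins, truth$eps$eps_del)
  flipped <- runif(m) < flip_p
  variants$out1 <- ifelse(flipped, der, anc)
  variants$out2 <- variants$out1
  variants$region <- "intergenic"
  structure(list(variants = variants,
                 exons = data.table::rbindlist(exon_rows),
                 callable = data.table::rbindlist(call_rows),
                 map_points = data.table::rbindlist(map_rows),
                 chrom_lengths = chrom_lengths,
                 truth = truth),
            class = "synth_genome")
}

#' Simulate a lineage-specific fixation table
#'
#' Draws `Poisson(rate * aligned_sites)` focal-lineage-unique fixation
#' events for every region x variant-type combination.
#'
#' @param rates data.frame with columns `region`, `vtype`, `rate`
#'   (per-site divergence rates, `>= 0`).
#' @param aligned_sites named vector of aligned sites per region (or one
#'   number for all).
#' @param seed integer seed.
#' @return data.table with one row per event: `region`, `vtype`,
#'   `lineage_specific = TRUE` (expanded event table suitable for
#'   [divergence()]).
#' @export
simulate_divergence <- function(rates, aligned_sites, seed = 1L) {
  dt <- data.table::as.data.table(rates)
  stopifnot(all(dt$rate >= 0))
  sites <- if (length(aligned_sites) == 1L && is.null(names(aligned_sites)))
    rep(aligned_sites, nrow(dt)) else unname(aligned_sites[dt$region])
  counts <- with_seed(seed, rpois(nrow(dt), dt$rate * sites))
  idx <- rep(seq_len(nrow(dt)), counts)
  if (length(idx) == 0L)
    return(data.table::data.table(region = character(), vtype = character(),
                                  lineage_specific = logical()))
  data.table::data.table(region = dt$region[idx], vtype = dt$vtype[idx],
                         lineage_specific = TRUE)
}
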