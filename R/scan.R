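#' @importFrom stats coef lm pt cor
#' @importFrom IRanges IRanges reduce restrict setdiff intersect findOverlaps
#'   width start end
NULL

#' Parsimony polarization against outgroup alleles
#'
#' Assigns the ancestral allele of a biallelic variant by strict parsimony:
#' all outgroup alleles must be identical AND equal to either the reference
#' or the alternate allele; anything else leaves the variant unpolarized.
#'
#' @param ref,alt allele strings.
#' @param outgroup_alleles character vector of outgroup alleles (at least
#'   one).
#' @return The ancestral allele string, or `NA_character_` if the variant
#'   cannot be polarized.
#' @export
polarize <- function(ref, alt, outgroup_alleles) {
  if (length(outgroup_alleles) == 0L)
    stop("at least one outgroup allele is required")
  u <- unique(outgroup_alleles)
  if (length(u) != 1L) return(NA_character_)
  if (u == ref || u == alt) return(u)
  NA_character_
}

#' Classify a polarized INDEL
#'
#' The derived allele (the one that is not ancestral) longer than the
#' ancestral allele makes the variant an insertion; shorter, a deletion.
#' Length is the absolute allele-length difference. Within CDS, a length
#' that is a multiple of three is in-frame, otherwise frameshift; outside
#' CDS the frame is not applicable.
#'
#' @param ref,alt allele strings.
#' @param ancestral the ancestral allele (must equal `ref` or `alt`).
#' @param region region class (`"CDS"`, `"intron"`, `"intergenic"`,
#'   `"AR"`, ...).
#' @return List with `vtype` (`"insertion"`/`"deletion"`), `length`, and
#'   `frame` (`"in_frame"`, `"frameshift"` or `"not_applicable"`).
#' @export
classify_indel <- function(ref, alt, ancestral, region = "intergenic") {
  if (!(ancestral %in% c(ref, alt)))
    stop("ancestral allele must be the reference or the alternate allele")
  derived <- if (ancestral == ref) alt else ref
  d <- nchar(derived) - nchar(ancestral)
  if (d == 0L) stop("alleles have equal length: not an INDEL")
  vtype <- if (d > 0L) "insertion" else "deletion"
  len <- abs(d)
  frame <- if (region == "CDS") {
    if (len %% 3L == 0L) "in_frame" else "frameshift"
  } else "not_applicable"
  list(vtype = vtype, length = len, frame = frame)
}

#' Hard post-calling filters
#'
#' Drops variants with site coverage more than twice or less than half the
#' sample mean coverage, INDELs longer than 50 bp, and INDELs at
#' multiallelic-by-length sites. Inequalities are strict: a variant exactly
#' at a boundary (coverage `2 x mean` or `0.5 x mean`, length exactly 50)
#' is retained.
#'
#' @param variants data.frame with columns `coverage`, `length`, and
#'   optionally `multiallelic` (logical).
#' @param mean_coverage sample mean depth.
#' @return List with `retained` (data.frame) and `rejected` (data.frame
#'   with a `reason` column).
#' @export
apply_filters <- function(variants, mean_coverage) {
  dt <- data.table::as.data.table(variants)
  reason <- rep(NA_character_, nrow(dt))
  if ("multiallelic" %in% names(dt))
    reason[is.na(reason) & dt$multiallelic] <- "multiallelic"
  reason[is.na(reason) & dt$coverage > 2 * mean_coverage] <- "coverage_high"
  reason[is.na(reason) & dt$coverage < 0.5 * mean_coverage] <- "coverage_low"
  reason[is.na(reason) & dt$length > 50] <- "length_gt_50"
  keep <- is.na(reason)
  rej <- dt[!keep]
  if (nrow(rej) > 0L) rej$reason <- reason[!keep]
  else rej$reason <- character(0)
  list(retained = dt[keep], rejected = rej)
}

#' Lineage-specific divergence per site
#'
#' Counts fixation events unique to the focal lineage and divides by the
#' number of sites aligned in all species, per region and variant type.
#' Events shared with an outgroup are not counted.
#'
#' @param fixation_table data.frame with columns `region`, `vtype`, and
#'   `lineage_specific` (logical), one row per fixation event.
#' @param aligned_sites named vector (or single number) of aligned sites
#'   per region.
#' @return data.table with columns `region`, `vtype`, `events`,
#'   `aligned_sites`, `rate`.
#' @export
divergence <- function(fixation_table, aligned_sites) {
  dt <- data.table::as.data.table(fixation_table)
  if (nrow(dt) == 0L)
    return(data.table::data.table(region = character(), vtype = character(),
                                  events = integer(),
                                  aligned_sites = numeric(),
                                  rate = numeric()))
  dt <- dt[dt$lineage_specific]
  res <- dt[, list(events = .N), by = c("region", "vtype")]
  res$aligned_sites <- if (length(aligned_sites) == 1L && is.null(names(aligned_sites)))
    rep(aligned_sites, nrow(res)) else unname(aligned_sites[res$region])
  if (any(is.na(res$aligned_sites) | res$aligned_sites == 0))
    stop("aligned site count missing or zero for some region")
  res$rate <- res$events / res$aligned_sites
  res[]
}

## ---- exon proximity -------------------------------------------------------

# per-chromosome interval sets whose positions lie at distance
# [w (b-1), w b) from the nearest merged exon edge, b = 1..n_bins
distance_bin_ranges <- function(exon_ir, chrom_len, bin_width, n_bins) {
  E <- IRanges::reduce(exon_ir)
  out <- vector("list", n_bins)
  prev <- E
  for (b in seq_len(n_bins)) {
    cur <- IRanges::restrict(
      IRanges::reduce(E + (bin_width * b - 1L)), 1L, as.integer(chrom_len))
    out[[b]] <- IRanges::setdiff(cur, prev)
    prev <- cur
  }
  out
}

#' Pool variants and callable sites into exon-distance bins
#'
#' Every noncoding position is assigned its distance to the nearest merged
#' exon edge; positions (variants and callable sites) are pooled
#' genome-wide into `n_bins` half-open distance bins
#' `[0, w), [w, 2w), ..., [ (n_bins-1) w, n_bins w )`. Positions inside
#' exons, or farther than `n_bins * w`, are excluded. Implemented with
#' interval arithmetic (nested exon expansions), so "nearest" exon is
#' handled exactly for positions between two exons.
#'
#' @param variants data.frame with `chrom`, `pos`, `vtype`,
#'   `derived_count`.
#' @param exons data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param callable data.frame of callable intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n haploid sample size (for the per-bin spectra).
#' @param bin_width,n_bins bin geometry (defaults: 2 kb bins to 100 kb).
#' @return Object of class `"exon_scan"`: `bins` (data.table with bin
#'   index, distance range, counts, callable sites, per-type `pi`) and
#'   `sfs` (list of per-bin [sfs_pair()]).
#' @export
exon_distance_bins <- function(variants, exons, callable, chrom_lengths,
                               n = 20L, bin_width = 2000L, n_bins = 50L) {
  variants <- data.table::as.data.table(variants)
  exons <- data.table::as.data.table(exons)
  callable <- data.table::as.data.table(callable)
  bin_var <- rep(NA_integer_, nrow(variants))
  bin_callable <- numeric(n_bins)
  for (ch in names(chrom_lengths)) {
    ex <- exons[exons$chrom == ch]
    if (nrow(ex) == 0L) next
    ir_ex <- IRanges::IRanges(ex$start, ex$end)
    bins <- distance_bin_ranges(ir_ex, chrom_lengths[[ch]], bin_width, n_bins)
    ca <- callable[callable$chrom == ch]
    ir_ca <- IRanges::reduce(IRanges::IRanges(ca$start, ca$end))
    vi <- which(variants$chrom == ch)
    ir_v <- IRanges::IRanges(variants$pos[vi], variants$pos[vi])
    for (b in seq_len(n_bins)) {
      bin_callable[b] <- bin_callable[b] +
        sum(IRanges::width(IRanges::intersect(bins[[b]], ir_ca)))
      hit <- IRanges::findOverlaps(ir_v, bins[[b]])
      bin_var[vi[S4Vectors::queryHits(hit)]] <- b
    }
  }
  sfs_list <- lapply(seq_len(n_bins), function(b) {
    vb <- variants[which(bin_var == b)]
    build_sfs(vb, n, max(bin_callable[b], 1), max(bin_callable[b], 1))
  })
  bins <- data.table::data.table(
    bin = seq_len(n_bins),
    d_lo = bin_width * (seq_len(n_bins) - 1),
    d_hi = bin_width * seq_len(n_bins),
    n_ins = vapply(sfs_list, function(p) sum(p$ins$counts), numeric(1)),
    n_del = vapply(sfs_list, function(p) sum(p$del$counts), numeric(1)),
    callable = bin_callable)
  bins$pi_ins <- vapply(sfs_list, function(p) pi_sfs(p$ins), numeric(1))
  bins$pi_del <- vapply(sfs_list, function(p) pi_sfs(p$del), numeric(1))
  structure(list(bins = bins, sfs = sfs_list,
                 variant_bin = bin_var,
                 bin_width = bin_width, n_bins = n_bins, n = n),
            class = "exon_scan")
}

#' Fit the gamma-DFE model to every distance bin
#'
#' Runs the variable-mutation-rate continuous-DFE model on each distance
#' bin's spectra against one shared neutral reference, and extracts the
#' per-type mutation-rate estimates. A bin whose fit fails (or which is
#' empty) is flagged and excluded from downstream correlations; the scan
#' continues.
#'
#' @param scan an `"exon_scan"` from [exon_distance_bins()].
#' @param neutral neutral-reference [sfs_pair()].
#' @param spec model family (default gamma DFE, variable mutation rates).
#' @param n_starts,seed passed to [fit_model()].
#' @param ... further arguments to [fit_model()].
#' @return data.table with per-bin `theta_ins`, `theta_del`, gamma-DFE
#'   parameters, `loglik`, `converged`, `ok`; fits attached as attribute
#'   `"fits"`.
#' @export
fit_bins <- function(scan, neutral, spec = dfe_model_spec("gamma", mutation_mode = "variable"),
                     n_starts = 3L, seed = 1L, ...) {
  stopifnot(inherits(scan, "exon_scan"))
  fits <- vector("list", scan$n_bins)
  rows <- lapply(seq_len(scan$n_bins), function(b) {
    pair <- scan$sfs[[b]]
    empty <- sum(pair$ins$counts) + sum(pair$del$counts) == 0
    fit <- if (empty) NULL else tryCatch(
      fit_model(dfe_data(neutral, pair), spec, n_starts = n_starts,
                seed = seed + b, ...),
      error = function(e) NULL)
    fits[[b]] <<- fit
    if (is.null(fit)) {
      data.table::data.table(bin = b, theta_ins = NA_real_,
                             theta_del = NA_real_, shape_ins = NA_real_,
                             shape_del = NA_real_, scale_ins = NA_real_,
                             scale_del = NA_real_, loglik = NA_real_,
                             converged = FALSE, ok = FALSE)
    } else {
      data.table::data.table(
        bin = b,
        theta_ins = fit$mle$theta_focal[["ins"]],
        theta_del = fit$mle$theta_focal[["del"]],
        shape_ins = fit$mle$shape[["ins"]], shape_del = fit$mle$shape[["del"]],
        scale_ins = fit$mle$scale[["ins"]], scale_del = fit$mle$scale[["del"]],
        loglik = fit$loglik, converged = fit$converged, ok = TRUE)
    }
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "fits", fits)
  out[]
}

#' Split a gamma-DFE mutation rate by selection band
#'
#' Partitions a continuous-DFE fit's per-type `theta` into the mass with
#' `0 <= |gamma| <= cut` (effectively neutral for `cut = 1`) and the mass
#' with `|gamma| > cut`, via the fitted gamma CDF. The two parts sum to
#' `theta` exactly.
#'
#' @param fit a gamma-family `"dfe_fit"`.
#' @param cut band boundary on `|gamma|` (default 1).
#' @return data.frame with one row per type: `theta`, `theta_neutral_band`,
#'   `theta_selected_band`.
#' @export
split_theta <- function(fit, cut = 1) {
  stopifnot(inherits(fit, "dfe_fit"))
  if (fit$spec$family != "gamma")
    stop("split_theta requires a continuous (gamma) DFE fit")
  rows <- lapply(c("ins", "del"), function(ty) {
    th <- fit$mle$theta_focal[[ty]]
    p <- gamma_mass(fit$mle$shape[[ty]], fit$mle$scale[[ty]], 0, cut)
    data.frame(type = ty, theta = th, theta_neutral_band = th * p,
               theta_selected_band = th * (1 - p))
  })
  do.call(rbind, rows)
}

## ---- rank correlations ----------------------------------------------------

avg_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; two-sided p-value from the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors (>= 3 paired observations, non-constant).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rho <- cor(avg_rank(x), avg_rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' First-order partial Spearman correlation
#'
#' Partial rank correlation of `x` and `y` controlling for `z`:
#' \deqn{\rho_{xy \cdot z} = \frac{\rho_{xy} - \rho_{xz}\rho_{yz}}
#'   {\sqrt{(1-\rho_{xz}^2)(1-\rho_{yz}^2)}}}
#' on average ranks, with a two-sided p-value from the t approximation on
#' `n - 3` degrees of freedom.
#'
#' @param x,y,z numeric vectors (>= 4 observations).
#' @return List with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  rxy <- cor(avg_rank(x), avg_rank(y))
  rxz <- cor(avg_rank(x), avg_rank(z))
  ryz <- cor(avg_rank(y), avg_rank(z))
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 0)
    stop("partial correlation undefined: confounder perfectly rank-",
         "correlated with x or y")
  rho <- (rxy - rxz * ryz) / sqrt(den)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 3)
  }
  list(rho = rho, p = p, n = n)
}

#' Progressive near-exon bin removal
#'
#' Re-tests a distance-ordered statistic against distance after removing
#' the nearest bin, then the two nearest, and so on, down to the farthest
#' two bins, to ask how far from exons a diversity-vs-distance trend
#' persists.
#'
#' @param distance vector of bin distances (sorted ascending).
#' @param statistic per-bin statistic (theta or pi).
#' @return data.table with `removed`, `n_bins`, `rho`, `p`.
#' @export
downsample_scan <- function(distance, statistic) {
  stopifnot(length(distance) == length(statistic), length(distance) >= 3L)
  nb <- length(distance)
  rows <- lapply(0:(nb - 2L), function(k) {
    idx <- (k + 1L):nb
    res <- if (length(idx) == 2L) {
      # two bins: the rank correlation is formally +/-1, no p-value exists
      list(rho = unname(sign(diff(statistic[idx]) * diff(distance[idx]))),
           p = NA_real_)
    } else {
      tryCatch(spearman_cor(distance[idx], statistic[idx]),
               error = function(e) list(rho = NA_real_, p = NA_real_))
    }
    data.table::data.table(removed = k, n_bins = length(idx),
                           rho = res$rho, p = res$p)
  })
  data.table::rbindlist(rows)
}

## ---- recombination --------------------------------------------------------

#' Fit per-chromosome cubic genetic maps
#'
#' Fits a third-order polynomial of map position (cM) on physical position
#' (bp) per chromosome; its derivative gives the local recombination rate.
#' A fitted map whose derivative dips negative anywhere on the data range
#' triggers a warning (rates are floored at zero on evaluation).
#'
#' @param map_points data.frame with columns `chrom`, `pos_bp`, `cM`.
#' @return Object of class `"linkage_map"`.
#' @export
fit_linkage_map <- function(map_points) {
  dt <- data.table::as.data.table(map_points)
  stopifnot(all(c("chrom", "pos_bp", "cM") %in% names(dt)))
  fits <- lapply(split(dt, dt$chrom), function(d) {
    if (nrow(d) < 4L)
      stop("chromosome ", d$chrom[1], ": need >= 4 map points for a cubic")
    fit <- lm(cM ~ poly(pos_bp, 3, raw = TRUE), data = d)
    cf <- unname(coef(fit))
    cf[is.na(cf)] <- 0
    rng <- range(d$pos_bp)
    xs <- seq(rng[1], rng[2], length.out = 200)
    deriv <- cf[2] + 2 * cf[3] * xs + 3 * cf[4] * xs^2
    if (any(deriv < 0))
      warning("chromosome ", d$chrom[1],
              ": fitted map has negative derivative on part of its range; ",
              "rates there will be floored at 0")
    list(coef = cf, range = rng)
  })
  structure(list(fits = fits), class = "linkage_map")
}

#' Point recombination rate from a fitted map
#'
#' Evaluates the derivative of the chromosome's fitted cubic at the given
#' positions, converted to cM/Mb. Negative derivatives are floored at 0
#' with a warning; positions outside the mapped range trigger an
#' extrapolation warning.
#'
#' @param map a `"linkage_map"`.
#' @param chrom chromosome id.
#' @param pos physical positions (bp), vectorized.
#' @return Recombination rates in cM/Mb.
#' @export
recomb_rate_at <- function(map, chrom, pos) {
  stopifnot(inherits(map, "linkage_map"))
  f <- map$fits[[as.character(chrom)]]
  if (is.null(f)) stop("no fitted map for chromosome ", chrom)
  if (any(pos < f$range[1] | pos > f$range[2]))
    warning("position(s) outside the mapped range on ", chrom,
            ": extrapolating the cubic")
  cf <- f$coef
  rate <- (cf[2] + 2 * cf[3] * pos + 3 * cf[4] * pos^2) * 1e6
  if (any(rate < 0)) {
    warning(sum(rate < 0), " negative fitted recombination rate(s) on ",
            chrom, " floored at 0")
    rate <- pmax(rate, 0)
  }
  unname(rate)
}

#' Mean recombination rate for a set of variants
#'
#' Point rate at every variant position and at 2 kb up- and downstream of
#' it (flanks clamped to the chromosome range), averaged over all
#' evaluations.
#'
#' @param map a `"linkage_map"`.
#' @param chrom chromosome id.
#' @param pos variant positions in the window.
#' @param chrom_len chromosome length (for clamping flanks).
#' @param flank flank offset (default 2000 bp).
#' @return Mean rate (cM/Mb).
#' @export
window_recomb_rate <- function(map, chrom, pos, chrom_len, flank = 2000L) {
  stopifnot(length(pos) >= 1L)
  at <- c(pmax(pos - flank, 1), pos, pmin(pos + flank, chrom_len))
  mean(suppressWarnings(recomb_rate_at(map, chrom, at)))
}

#' Nonoverlapping-window diversity vs recombination scan
#'
#' Tiles each chromosome into nonoverlapping windows, and per window
#' computes insertion/deletion diversity (`pi`), Tajima's D, per-site
#' divergence, and the mean recombination rate from the fitted map.
#' Windows with fewer polarizable INDELs than `min_indels` are dropped
#' (the boundary is inclusive: exactly `min_indels` is kept).
#'
#' @param variants polarized noncoding INDELs: data.frame with `chrom`,
#'   `pos`, `vtype`, `derived_count`.
#' @param map a `"linkage_map"`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param callable callable intervals (`chrom`, `start`, `end`).
#' @param n haploid sample size.
#' @param fixations optional data.frame of fixation events (`chrom`,
#'   `pos`) for per-window divergence; aligned sites are taken as the
#'   window's callable sites.
#' @param window window size in bp (default 2 Mb).
#' @param min_indels minimum polarizable INDELs per retained window.
#' @return data.table of per-window results.
#' @export
recomb_windows <- function(variants, map, chrom_lengths, callable, n = 20L,
                           fixations = NULL, window = 2e6, min_indels = 500L) {
  variants <- data.table::as.data.table(variants)
  callable <- data.table::as.data.table(callable)
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = window)
    ca <- callable[callable$chrom == ch]
    ir_ca <- IRanges::reduce(IRanges::IRanges(ca$start, ca$end))
    vch <- variants[variants$chrom == ch]
    fch <- if (!is.null(fixations)) {
      fx <- data.table::as.data.table(fixations)
      fx[fx$chrom == ch]
    } else NULL
    for (ws in starts) {
      we <- min(ws + window - 1, len)
      vw <- vch[vch$pos >= ws & vch$pos <= we]
      if (nrow(vw) < min_indels) next
      cw <- sum(IRanges::width(IRanges::intersect(
        ir_ca, IRanges::IRanges(as.integer(ws), as.integer(we)))))
      cw <- max(cw, 1)
      pair <- build_sfs(vw, n, cw, cw)
      div <- if (!is.null(fch)) {
        sum(fch$pos >= ws & fch$pos <= we) / cw
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = ch, start = ws, end = we,
        n_indels = nrow(vw), callable = cw,
        pi_ins = pi_sfs(pair$ins), pi_del = pi_sfs(pair$del),
        tajd_ins = tajimas_d(pair$ins), tajd_del = tajimas_d(pair$del),
        divergence = div,
        recomb_rate = window_recomb_rate(map, ch, vw$pos, len))
    }
  }
  if (length(rows) == 0L)
    return(data.table::data.table())
  data.table::rbindlist(rows)
}
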