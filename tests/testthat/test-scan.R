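test_that("parsimony polarization rule", {
  expect_equal(polarize("A", "AT", c("A", "A")), "A")
  expect_true(is.na(polarize("A", "AT", c("A", "AT"))))
  expect_true(is.na(polarize("A", "AT", c("G", "G"))))
  expect_equal(polarize("AT", "A", c("AT", "AT", "AT")), "AT")
  expect_error(polarize("A", "AT", character(0)), "outgroup")
})

test_that("INDEL classification: direction, length, frame", {
  c1 <- classify_indel("A", "ATTT", "A", "CDS")
  expect_equal(c1, list(vtype = "insertion", length = 3, frame = "in_frame"))
  c2 <- classify_indel("ATT", "A", "ATT", "CDS")
  expect_equal(c2, list(vtype = "deletion", length = 2, frame = "frameshift"))
  c3 <- classify_indel("ATT", "A", "ATT", "intron")
  expect_equal(c3$frame, "not_applicable")
  # ancestral = alt: the REF allele is derived
  c4 <- classify_indel("ATT", "A", "A", "CDS")
  expect_equal(c4$vtype, "insertion")
  expect_error(classify_indel("AT", "GC", "AT"), "equal length")
  expect_error(classify_indel("A", "AT", "G"), "ancestral")
})

test_that("hard filters use strict inequalities and tag rejections", {
  v <- data.frame(coverage = c(100, 88, 44, 22, 21, 44, 44),
                  length = c(1, 1, 1, 1, 1, 50, 51),
                  multiallelic = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                   FALSE, FALSE))
  out <- apply_filters(v, mean_coverage = 44)
  expect_equal(nrow(out$retained), 4) # 88, 44, 22, len-50 kept; 100, 21, 51 out
  expect_setequal(out$rejected$reason,
                  c("coverage_high", "coverage_low", "length_gt_50"))
  vm <- data.frame(coverage = 44, length = 1, multiallelic = TRUE)
  expect_equal(apply_filters(vm, 44)$rejected$reason, "multiallelic")
})

test_that("divergence counts lineage-specific events per aligned site", {
  tab <- data.frame(region = rep("CDS", 7), vtype = rep("deletion", 7),
                    lineage_specific = c(rep(TRUE, 5), FALSE, FALSE))
  d <- divergence(tab, c(CDS = 1e6))
  expect_equal(d$rate, 5e-6)
  expect_equal(d$events, 5)
  empty <- divergence(data.frame(region = character(), vtype = character(),
                                 lineage_specific = logical()), 100)
  expect_equal(nrow(empty), 0)
})

test_that("exon-distance bins tile [0, 100kb) exactly and assign correctly", {
  chrom_lengths <- c(chrA = 500000L)
  exons <- data.frame(chrom = "chrA", start = 240001L, end = 240200L)
  callable <- data.frame(chrom = "chrA", start = 1L, end = 500000L)
  v <- data.frame(chrom = "chrA",
                  pos = c(240201L,          # 1 bp away -> bin 1
                          240200L + 1999L,  # 1999 -> bin 1
                          240200L + 2000L,  # 2000 -> bin 2
                          240001L - 99999L, # 99999 left -> bin 50
                          240201L + 100000L), # 100000 -> excluded
                  vtype = "deletion", derived_count = 1L)
  scan <- exon_distance_bins(v, exons, callable, chrom_lengths, n = 4,
                             bin_width = 2000L, n_bins = 50L)
  expect_equal(scan$variant_bin, c(1L, 1L, 2L, 50L, NA))
  expect_equal(scan$bins$d_lo, 2000 * (0:49))
  # variant between two exons takes the nearer one
  exons2 <- data.frame(chrom = "chrA", start = c(100001L, 140001L),
                       end = c(100100L, 140100L))
  v2 <- data.frame(chrom = "chrA", pos = 139000L, # 1001 bp to right exon
                   vtype = "insertion", derived_count = 1L)
  s2 <- exon_distance_bins(v2, exons2, callable, chrom_lengths, n = 4)
  expect_equal(s2$variant_bin, 1L)
  # callable sites conserved: bins partition the <=100kb noncoding zone
  total_near <- sum(s2$bins$callable)
  ir_ex <- IRanges::reduce(IRanges::IRanges(exons2$start, exons2$end))
  near <- IRanges::restrict(IRanges::reduce(ir_ex + 99999L), 1L, 500000L)
  expect_equal(total_near,
               sum(IRanges::width(near)) - sum(IRanges::width(ir_ex)))
})

test_that("per-bin spectra feed the DFE machinery and split_theta partitions", {
  tr <- synth_genome_truth(n_chrom = 2, chrom_len = 1e6, tau = 0, seed = 17)
  g <- simulate_genome(tr)
  scan <- exon_distance_bins(g$variants, g$exons, g$callable,
                             g$chrom_lengths, n = 20, n_bins = 6L)
  neutral <- sfs_pair(sfs(round(200 / (1:19)), 20, 1e6),
                      sfs(round(340 / (1:19)), 20, 1e6))
  fb <- fit_bins(scan, neutral, n_starts = 1, seed = 3)
  expect_equal(nrow(fb), 6)
  expect_true(all(fb$ok[scan$bins$n_ins + scan$bins$n_del > 0]))
  fits <- attr(fb, "fits")
  f1 <- fits[[which(fb$ok)[1]]]
  sp <- split_theta(f1)
  expect_equal(sp$theta_neutral_band + sp$theta_selected_band, sp$theta)
  # a DFE far above the cut puts no mass in the neutral band
  fake <- structure(list(spec = dfe_model_spec("gamma"),
                         mle = list(theta_focal = c(ins = 1e-4, del = 1e-4),
                                    shape = c(ins = 100, del = 100),
                                    scale = c(ins = 10, del = 10))),
                    class = "dfe_fit")
  spf <- split_theta(fake)
  expect_lt(max(spf$theta_neutral_band), 1e-10)
})

test_that("spearman and partial spearman match independent oracles", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12); z <- rnorm(12)
    s <- spearman_cor(x, y)
    o <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(s$rho, unname(o$estimate), tolerance = 1e-12)
    expect_equal(s$p, o$p.value, tolerance = 1e-10)
    # rank-residualization oracle for the partial correlation
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
    ps <- partial_spearman(x, y, z)
    expect_equal(ps$rho, unname(cor(ex, ey)), tolerance = 1e-10)
  }
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  # independent confounder reduces to the plain correlation
  x <- c(3, 1, 4, 1, 5, 9, 2, 6); y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  z_ind <- c(1, -1, 1, -1, 1, -1, 1, -1) * 0 + c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  # construct z with zero rank correlation to both by symmetry is fiddly;
  # instead verify the formula reduction directly
  ps <- partial_spearman(x, y, seq_along(x))
  rxy <- spearman_cor(x, y)$rho
  rxz <- spearman_cor(x, seq_along(x))$rho
  ryz <- spearman_cor(y, seq_along(x))$rho
  expect_equal(ps$rho, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)))
  expect_error(partial_spearman(x, 2 * x + 1, x), "undefined")
})

test_that("downsampling removes bins progressively without touching survivors", {
  d <- 2000 * (1:50)
  theta <- 1e-4 * (1 - exp(-d / 25000))
  tab <- downsample_scan(d, theta)
  expect_equal(nrow(tab), 49)
  expect_equal(tab$n_bins, 50:2)
  expect_true(all(abs(tab$rho - 1) < 1e-12))
  expect_true(is.na(tab$p[tab$n_bins == 2]))
  expect_true(all(tab$p[tab$n_bins > 2] < 0.05))
  # immutability: rerunning gives identical results
  expect_identical(tab, downsample_scan(d, theta))
})

test_that("cubic map fitting recovers derivatives exactly and flags issues", {
  pts <- data.frame(chrom = "c1", pos_bp = seq(0, 5e6, by = 5e5))
  pts$cM <- 2e-6 * pts$pos_bp # y = 2x in cM/Mb terms
  map <- fit_linkage_map(pts)
  expect_equal(recomb_rate_at(map, "c1", c(1e6, 3e6)), c(2, 2),
               tolerance = 1e-9)
  # exact recovery of a known cubic's derivative at interior points
  cf <- c(1, 3e-6, -4e-13, 5e-20)
  pts2 <- data.frame(chrom = "c2", pos_bp = seq(0, 5e6, by = 2.5e5))
  pts2$cM <- cf[1] + cf[2] * pts2$pos_bp + cf[3] * pts2$pos_bp^2 +
    cf[4] * pts2$pos_bp^3
  map2 <- fit_linkage_map(pts2)
  at <- c(5e5, 2.2e6, 4.1e6)
  truth <- (cf[2] + 2 * cf[3] * at + 3 * cf[4] * at^2) * 1e6
  expect_equal(recomb_rate_at(map2, "c2", at), truth, tolerance = 1e-8)
  # chromosomes are independent
  both <- fit_linkage_map(rbind(pts, pts2))
  expect_equal(recomb_rate_at(both, "c1", 1e6), 2, tolerance = 1e-9)
  expect_error(fit_linkage_map(data.frame(chrom = "x", pos_bp = 1:3,
                                          cM = 1:3)), ">= 4")
  expect_warning(recomb_rate_at(map, "c1", 6e6), "extrapolat")
  # negative derivative floored with warning
  dec <- data.frame(chrom = "d1", pos_bp = seq(0, 1e6, by = 1e5))
  dec$cM <- 5 - 3e-6 * dec$pos_bp
  expect_warning(mapd <- fit_linkage_map(dec), "negative")
  expect_warning(r <- recomb_rate_at(mapd, "d1", 5e5), "floored")
  expect_equal(r, 0)
})

test_that("window recombination rate averages variant and flank evaluations", {
  pts <- data.frame(chrom = "c1", pos_bp = seq(0, 5e6, by = 5e5))
  pts$cM <- 2e-6 * pts$pos_bp
  map <- fit_linkage_map(pts)
  expect_equal(window_recomb_rate(map, "c1", c(1e6, 2e6), 5e6), 2,
               tolerance = 1e-9)
  # single variant: mean of exactly 3 evaluations, brute-forced
  cf <- c(0, 1e-6, 1e-13, 0)
  pts2 <- data.frame(chrom = "c2", pos_bp = seq(0, 5e6, by = 2.5e5))
  pts2$cM <- cf[2] * pts2$pos_bp + cf[3] * pts2$pos_bp^2
  map2 <- fit_linkage_map(pts2)
  pos <- c(1e6, 1.5e6, 2e6, 2.5e6, 3e6)
  brute <- mean(vapply(pos, function(p) {
    mean((cf[2] + 2 * cf[3] * c(p - 2000, p, p + 2000)) * 1e6)
  }, numeric(1)))
  # brute mean over the 3 evaluations of each of the 5 variants
  got <- window_recomb_rate(map2, "c2", pos, 5e6)
  expect_equal(got, brute, tolerance = 1e-9)
})

test_that("recombination windows honor the polarizable-INDEL floor", {
  set.seed(23)
  chrom_lengths <- c(w1 = 1e6)
  pts <- data.frame(chrom = "w1", pos_bp = seq(0, 1e6, by = 1e5))
  pts$cM <- 3e-6 * pts$pos_bp
  map <- fit_linkage_map(pts)
  callable <- data.frame(chrom = "w1", start = 1L, end = 1e6)
  mkv <- function(m, lo, hi) data.frame(
    chrom = "w1", pos = sort(sample(lo:hi, m)),
    vtype = sample(c("insertion", "deletion"), m, replace = TRUE),
    derived_count = sample(1:19, m, replace = TRUE))
  v <- rbind(mkv(499, 1, 5e5), mkv(500, 5e5 + 1, 1e6))
  w <- recomb_windows(v, map, chrom_lengths, callable, n = 20,
                      window = 5e5, min_indels = 500L)
  expect_equal(nrow(w), 1) # 499-variant window excluded, 500 kept
  expect_equal(w$n_indels, 500)
  expect_equal(w$recomb_rate, 3, tolerance = 1e-8)
  expect_gt(w$pi_del, 0)
})
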