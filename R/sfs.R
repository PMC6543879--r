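#' Unfolded site frequency spectrum
#'
#' Container for an unfolded (polarized) site frequency spectrum: the number
#' of segregating variants observed at each derived-allele count
#' \eqn{i = 1, \dots, n-1} in a sample of \eqn{n} chromosomes, together with
#' the number of callable sites used as the denominator for per-site rates.
#' Counts may be non-integer: the orientation-error correction
#' ([correct_sfs()]) returns real-valued spectra.
#'
#' @param counts numeric vector of length `n - 1`; `counts[i]` is the number
#'   of segregating variants with derived-allele count `i`. All entries must
#'   be non-negative.
#' @param n haploid sample size (number of chromosomes), at least 2.
#' @param callable_sites positive number of sites at which a variant could
#'   have been called (the per-site denominator).
#' @return An object of class `"sfs"`.
#' @seealso [sfs_pair()], [pi_sfs()], [tajimas_d()]
#' @export
sfs <- function(counts, n, callable_sites = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("sample size n must be at least 2")
  counts <- as.numeric(counts)
  if (length(counts) != n - 1L)
    stop("counts must have exactly n - 1 entries (got ", length(counts),
         ", expected ", n - 1L, ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.numeric(callable_sites) || length(callable_sites) != 1L ||
      callable_sites < 1)
    stop("callable_sites must be a single number >= 1")
  structure(list(counts = counts, n = n, callable_sites = callable_sites),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("Unfolded SFS: n =", x$n, ", S =", sum(x$counts),
      ", L =", format(x$callable_sites), "\n")
  invisible(x)
}

#' Paired insertion/deletion spectra
#'
#' Insertions and deletions polarized against the same outgroups share a
#' sample size and are coupled by ancestral-state misidentification: a
#' misoriented insertion at derived count \eqn{i} appears as a deletion at
#' count \eqn{n - i} and vice versa. This pairing is what the linear
#' correction in [correct_sfs()] operates on.
#'
#' @param ins,del [sfs()] objects for insertions and deletions; must share `n`.
#' @return An object of class `"sfs_pair"`.
#' @export
sfs_pair <- function(ins, del) {
  stopifnot(inherits(ins, "sfs"), inherits(del, "sfs"))
  if (ins$n != del$n)
    stop("insertion and deletion spectra must share the sample size n")
  structure(list(ins = ins, del = del), class = "sfs_pair")
}

#' @export
print.sfs_pair <- function(x, ...) {
  cat("Polarized SFS pair: n =", x$ins$n,
      ", S_ins =", sum(x$ins$counts),
      ", S_del =", sum(x$del$counts), "\n")
  invisible(x)
}

#' Ancestral-state misidentification probabilities
#'
#' `eps_ins` (`eps_del`) is the probability that a true insertion (deletion)
#' has its ancestral state misassigned, so that it is recorded as a deletion
#' (insertion) at the complementary frequency. The 2x2 mixing system is
#' invertible iff `eps_ins + eps_del < 1`.
#'
#' @param eps_ins,eps_del probabilities in `[0, 1)` with sum below 1.
#' @return An object of class `"orientation_errors"`.
#' @export
orientation_errors <- function(eps_ins, eps_del) {
  stopifnot(is.numeric(eps_ins), is.numeric(eps_del),
            length(eps_ins) == 1L, length(eps_del) == 1L)
  if (eps_ins < 0 || eps_del < 0 || eps_ins >= 1 || eps_del >= 1)
    stop("error probabilities must lie in [0, 1)")
  if (eps_ins + eps_del >= 1)
    stop("eps_ins + eps_del must be < 1 (the mixing system is singular ",
         "when the probabilities sum to 1)")
  structure(list(eps_ins = eps_ins, eps_del = eps_del),
            class = "orientation_errors")
}

#' Tally polarized variants into an insertion/deletion SFS pair
#'
#' @param variants data.frame with at least columns `vtype`
#'   (`"insertion"`/`"deletion"`) and `derived_count` (integer in
#'   `1..n-1`). Unpolarized variants or fixed/absent counts are rejected.
#' @param n haploid sample size.
#' @param callable_ins,callable_del callable-site denominators per type.
#' @return An [sfs_pair()].
#' @export
build_sfs <- function(variants, n, callable_ins = 1, callable_del = 1) {
  n <- as.integer(n)
  if (nrow(variants) == 0L) {
    return(sfs_pair(sfs(numeric(n - 1L), n, callable_ins),
                    sfs(numeric(n - 1L), n, callable_del)))
  }
  vt <- as.character(variants$vtype)
  dc <- as.integer(variants$derived_count)
  if (any(!vt %in% c("insertion", "deletion")))
    stop("all variants must be polarized insertions or deletions")
  if (any(dc < 1L | dc > n - 1L))
    stop("derived counts must lie in 1..n-1: fixed (i = n) or absent ",
         "(i = 0) alleles are not polymorphisms")
  tally <- function(type) {
    tabulate(dc[vt == type], nbins = n - 1L)
  }
  sfs_pair(sfs(tally("insertion"), n, callable_ins),
           sfs(tally("deletion"), n, callable_del))
}

# shared forward mixing map of Eqs-style misorientation:
# obs_ins[i]   = (1-e_ins) ins[i]   + e_del del[n-i]
# obs_del[n-i] = (1-e_del) del[n-i] + e_ins ins[i]
mix_spectra <- function(ins_counts, del_counts, errors) {
  ei <- errors$eps_ins
  ed <- errors$eps_del
  list(ins = (1 - ei) * ins_counts + ed * rev(del_counts),
       del = (1 - ed) * del_counts + ei * rev(ins_counts))
}

#' Forward misorientation: true spectra to observed spectra
#'
#' Applies the linear ancestral-state misidentification map. With
#' probability `eps_ins` an insertion at derived count \eqn{i} is recorded
#' as a deletion at count \eqn{n - i} (and symmetrically for deletions), so
#' the observed spectra are a 2x2 linear mixture of the true ones at each
#' paired frequency \eqn{(i, n - i)}. Total segregating counts are
#' conserved.
#'
#' @param pair true [sfs_pair()].
#' @param errors [orientation_errors()].
#' @return Observed-scale [sfs_pair()].
#' @export
apply_misorientation <- function(pair, errors) {
  stopifnot(inherits(pair, "sfs_pair"), inherits(errors, "orientation_errors"))
  m <- mix_spectra(pair$ins$counts, pair$del$counts, errors)
  sfs_pair(sfs(m$ins, pair$ins$n, pair$ins$callable_sites),
           sfs(m$del, pair$del$n, pair$del$callable_sites))
}

#' Correct observed spectra for misorientation
#'
#' Inverts the misorientation map by solving, for each frequency
#' \eqn{1 \le i < n}, the 2x2 linear system pairing the observed insertion
#' count at \eqn{i} with the observed deletion count at \eqn{n - i}. The
#' system is non-singular iff `eps_ins + eps_del < 1` (determinant
#' `1 - eps_ins - eps_del`). Solutions can be negative when the observed
#' counts are noisy; negative entries are clipped to zero with a warning,
#' since downstream statistics require non-negative spectra.
#'
#' @param observed observed-scale [sfs_pair()].
#' @param errors [orientation_errors()].
#' @return Corrected (true-scale) [sfs_pair()]; entries are reals.
#' @export
correct_sfs <- function(observed, errors) {
  stopifnot(inherits(observed, "sfs_pair"),
            inherits(errors, "orientation_errors"))
  ei <- errors$eps_ins
  ed <- errors$eps_del
  det <- 1 - ei - ed
  if (det <= 0) stop("singular system: eps_ins + eps_del >= 1")
  oi <- observed$ins$counts
  od <- observed$del$counts
  ins <- ((1 - ed) * oi - ed * rev(od)) / det
  del <- ((1 - ei) * od - ei * rev(oi)) / det
  # warn only for materially negative solutions, not rounding residue
  tol <- 1e-8 * max(1, max(abs(oi)), max(abs(od)))
  n_neg <- sum(ins < -tol) + sum(del < -tol)
  if (n_neg > 0) {
    warning(n_neg, " corrected SFS entr", if (n_neg == 1) "y" else "ies",
            " negative; clipped to 0")
  }
  ins <- pmax(ins, 0)
  del <- pmax(del, 0)
  sfs_pair(sfs(ins, observed$ins$n, observed$ins$callable_sites),
           sfs(del, observed$del$n, observed$del$callable_sites))
}

#' Per-site pairwise diversity from an unfolded SFS
#'
#' \deqn{\pi = \frac{1}{L}\sum_i \frac{2 i (n-i)}{n(n-1)} \, \xi_i}
#' Each segregating INDEL contributes as a single mutation event regardless
#' of its length (diversity in events per callable site, not per base pair
#' affected).
#'
#' @param x an [sfs()].
#' @return Per-site diversity (non-negative scalar).
#' @export
pi_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"))
  n <- x$n
  i <- seq_len(n - 1L)
  sum(2 * i * (n - i) / (n * (n - 1)) * x$counts) / x$callable_sites
}

#' Watterson's estimator per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param x an [sfs()].
#' @return Per-site Watterson theta.
#' @export
watterson_theta <- function(x) {
  stopifnot(inherits(x, "sfs"))
  a1 <- sum(1 / seq_len(x$n - 1L))
  sum(x$counts) / (a1 * x$callable_sites)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from an unfolded SFS
#'
#' Standard standardized difference between mean pairwise diversity and
#' Watterson's estimator, computed from the (unfolded) counts. With no
#' segregating sites the statistic is undefined and `NA` is returned (an
#' explicit sentinel, never silently zero).
#'
#' @param x an [sfs()].
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(x) {
  stopifnot(inherits(x, "sfs"))
  S <- sum(x$counts)
  if (S == 0) return(NA_real_)
  n <- x$n
  i <- seq_len(n - 1L)
  k <- tajima_constants(n)
  pi_tot <- sum(2 * i * (n - i) / (n * (n - 1)) * x$counts)
  (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Summary statistics for one spectrum
#'
#' @param x an [sfs()].
#' @return List with `pi`, `tajimas_d`, `segregating_sites`,
#'   `watterson_theta`. `tajimas_d` is `NA` when no sites segregate.
#' @export
summary_stats <- function(x) {
  stopifnot(inherits(x, "sfs"))
  list(pi = pi_sfs(x),
       tajimas_d = tajimas_d(x),
       segregating_sites = sum(x$counts),
       watterson_theta = watterson_theta(x))
}

#' Length-stratified summary statistics
#'
#' Groups polarized variants by type and event length `|len(alt) -
#' len(ref)|` and computes per-group diversity statistics. All groups share
#' the supplied callable-site denominator.
#'
#' @param variants data.frame with columns `vtype`, `derived_count`,
#'   `length`.
#' @param n haploid sample size.
#' @param callable_sites shared per-site denominator.
#' @return data.table with one row per (vtype, length) group: `S`, `pi`,
#'   `tajimas_d`, `watterson_theta`. Groups with `S = 0` never appear (a
#'   group exists only if a variant was observed in it).
#' @export
stats_by_length <- function(variants, n, callable_sites = 1) {
  stopifnot(all(c("vtype", "derived_count", "length") %in% names(variants)))
  dt <- data.table::as.data.table(variants)
  dt <- dt[dt$vtype %in% c("insertion", "deletion")]
  grp <- dt[, {
    s <- sfs(tabulate(.SD$derived_count, nbins = n - 1L), n, callable_sites)
    list(S = sum(s$counts), pi = pi_sfs(s), tajimas_d = tajimas_d(s),
         watterson_theta = watterson_theta(s))
  }, by = c("vtype", "length")]
  data.table::setorderv(grp, c("vtype", "length"))
  grp[]
}

#' Proportion of in-frame INDELs per gene
#'
#' A coding INDEL is in-frame when its length is a multiple of three.
#' Genes without any INDEL are omitted (no proportion is defined for them).
#'
#' @param variants data.frame with columns `gene` and `length`.
#' @return data.table with columns `gene`, `n_indels`, `prop_in_frame`.
#' @export
in_frame_proportion <- function(variants) {
  stopifnot(all(c("gene", "length") %in% names(variants)))
  dt <- data.table::as.data.table(variants)
  if (nrow(dt) == 0L)
    return(data.table::data.table(gene = character(), n_indels = integer(),
                                  prop_in_frame = numeric()))
  res <- dt[, list(n_indels = .N,
                   prop_in_frame = mean(.SD$length %% 3L == 0L)),
            by = "gene"]
  data.table::setorderv(res, "gene")
  res[]
}

#' Write / read an SFS pair as TSV
#'
#' Plain-text serialization: comment header lines carry `n` and the
#' callable-site denominators; the body has columns `type`, `i`, `count`.
#'
#' @param pair an [sfs_pair()].
#' @param path output file.
#' @return `write_sfs_pair` returns `path` invisibly; `read_sfs_pair`
#'   returns the [sfs_pair()].
#' @export
write_sfs_pair <- function(pair, path) {
  stopifnot(inherits(pair, "sfs_pair"))
  hdr <- c(sprintf("#n=%d", pair$ins$n),
           sprintf("#callable_ins=%.10g", pair$ins$callable_sites),
           sprintf("#callable_del=%.10g", pair$del$callable_sites),
           "type\ti\tcount")
  n1 <- pair$ins$n - 1L
  body <- c(sprintf("insertion\t%d\t%.10g", seq_len(n1), pair$ins$counts),
            sprintf("deletion\t%d\t%.10g", seq_len(n1), pair$del$counts))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_sfs_pair
#' @export
read_sfs_pair <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_num <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(ln) != 1L) stop("missing header field: ", key)
    as.numeric(sub(".*=", "", ln))
  }
  n <- as.integer(get_num("n"))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  pick <- function(type) {
    sub <- tab[tab$type == type, ]
    counts <- numeric(n - 1L)
    counts[sub$i] <- sub$count
    counts
  }
  sfs_pair(sfs(pick("insertion"), n, get_num("callable_ins")),
           sfs(pick("deletion"), n, get_num("callable_del")))
}
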