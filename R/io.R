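#' @importFrom utils read.delim write.table modifyList
NULL

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the defaults used
#' throughout: 2-kb exon-distance bins to 100 kb, 2-Mb recombination
#' windows with a 500-INDEL floor, n = 20 chromosomes, 128 quadrature
#' nodes, 100 gamma-DFE bins, 10 optimizer starts. Serialized as JSON next
#' to every output for provenance.
#'
#' @param ... overrides of the defaults.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(n = 20L, bin_width = 2000L, max_distance = 100000L,
              window = 2e6, min_indels = 500L, quad_nodes = 128L,
              gamma_bins = 100L, n_starts = 10L, seed = 1L,
              indel_max_length = 50L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "run_config")
}

#' @rdname run_config
#' @param config a `"run_config"`.
#' @param path output JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read variants from VCF and join a polarization table
#'
#' Parses a VCF (via `vcfR`), extracts position, alleles and the
#' ALT-allele count (`AC`/`AN` INFO fields), joins the outgroup-allele
#' table by (chrom, pos, ref, alt), and polarizes each variant by
#' parsimony ([polarize()]). Variants missing from the polarization table,
#' or with discordant outgroups, are kept but flagged `unpolarized` (with
#' a warning tallying them). A contig present in the table but absent from
#' the VCF is treated as an input inconsistency and raises an error.
#'
#' @param vcf_path VCF file (plain text or bgzipped).
#' @param polarization_tsv TSV with columns `chrom`, `pos`, `ref`, `alt`,
#'   and one column per outgroup (named `out*`).
#' @param n haploid sample size (`AN` consistency check).
#' @return data.table of variant records: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `vtype`, `derived_count`, `length`, `ancestral`.
#' @export
read_variants <- function(vcf_path, polarization_tsv, n = 20L) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dt <- data.table::data.table(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    alt_count = as.integer(vcfR::extract.info(v, "AC")))
  pol <- data.table::as.data.table(
    read.delim(polarization_tsv, stringsAsFactors = FALSE))
  out_cols <- grep("^out", names(pol), value = TRUE)
  if (length(out_cols) == 0L) stop("polarization table has no out* columns")
  extra <- setdiff(unique(pol$chrom), unique(dt$chrom))
  if (length(extra) > 0L)
    stop("contig(s) in polarization table but not in VCF: ",
         paste(extra, collapse = ", "))
  merged <- merge(dt, pol, by = c("chrom", "pos", "ref", "alt"),
                  all.x = TRUE, sort = FALSE)
  anc <- vapply(seq_len(nrow(merged)), function(i) {
    og <- unlist(merged[i, out_cols, with = FALSE], use.names = FALSE)
    og <- og[!is.na(og)]
    if (length(og) == 0L) return(NA_character_)
    polarize(merged$ref[i], merged$alt[i], og)
  }, character(1))
  n_unpol <- sum(is.na(anc))
  if (n_unpol > 0L)
    warning(n_unpol, " variant(s) could not be polarized ",
            "(missing from table or discordant outgroups)")
  merged$ancestral <- anc
  merged$length <- abs(nchar(merged$alt) - nchar(merged$ref))
  merged$vtype <- "unpolarized"
  pol_ok <- !is.na(anc) & merged$length > 0L
  if (any(pol_ok)) {
    der_longer <- ifelse(merged$ancestral[pol_ok] == merged$ref[pol_ok],
                         nchar(merged$alt[pol_ok]) > nchar(merged$ref[pol_ok]),
                         nchar(merged$ref[pol_ok]) > nchar(merged$alt[pol_ok]))
    merged$vtype[pol_ok] <- ifelse(der_longer, "insertion", "deletion")
  }
  merged$derived_count <- ifelse(
    merged$vtype == "unpolarized", NA_integer_,
    ifelse(merged$ancestral == merged$ref, merged$alt_count,
           n - merged$alt_count))
  data.table::setcolorder(
    merged, c("chrom", "pos", "ref", "alt", "alt_count", "vtype",
              "derived_count", "length", "ancestral"))
  merged[]
}

#' Write a simulated genome to standard files
#'
#' Emits VCF 4.2 (variants, with `AC`/`AN` INFO), GFF3 (exons), BED
#' (0-based half-open callable intervals), TSVs (polarization table and
#' linkage map), and the generating truth as JSON. Reading the files back
#' reproduces the in-memory objects.
#'
#' @param g a `"synth_genome"` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_genome_files <- function(g, dir) {
  stopifnot(inherits(g, "synth_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- g$variants
  n <- g$truth$n
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             gff = file.path(dir, "exons.gff3"),
             bed = file.path(dir, "callable.bed"),
             pol = file.path(dir, "polarization.tsv"),
             map = file.path(dir, "linkage_map.tsv"),
             truth = file.path(dir, "truth.json"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(g$chrom_lengths),
                   as.integer(g$chrom_lengths)),
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
                  v$chrom, v$pos, v$ref, v$alt, v$alt_count, n)
  writeLines(c(hdr, body), paths[["vcf"]])
  gff <- c("##gff-version 3",
           sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tID=exon%06d",
                   g$exons$chrom, g$exons$start, g$exons$end,
                   seq_len(nrow(g$exons))))
  writeLines(gff, paths[["gff"]])
  writeLines(sprintf("%s\t%d\t%d", g$callable$chrom,
                     g$callable$start - 1L, g$callable$end),
             paths[["bed"]])
  pol <- v[, c("chrom", "pos", "ref", "alt", "out1", "out2"), with = FALSE]
  write.table(pol, paths[["pol"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(g$map_points, paths[["map"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- g$truth
  tr$map_coef <- lapply(seq_len(tr$n_chrom), tr$map_coef)
  tr$eps <- unclass(tr$eps)
  tr$theta_max <- as.list(tr$theta_max) # keep names through JSON
  jsonlite::write_json(unclass(tr), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read simple interval and table inputs
#'
#' `read_bed` reads 0-based half-open BED into 1-based inclusive
#' intervals; `read_gff_exons` extracts exon features from a GFF3;
#' `read_linkage_map` and `read_polarization_table` read the TSV layouts
#' written by [write_genome_files()].
#'
#' @param path input file.
#' @return data.table.
#' @export
read_bed <- function(path) {
  dt <- data.table::as.data.table(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE))
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  dt$start <- dt$start + 1L # to 1-based inclusive
  dt[]
}

#' @rdname read_bed
#' @export
read_gff_exons <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  f <- data.table::as.data.table(
    read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE))
  f <- f[f$V3 == "exon"]
  data.table::data.table(chrom = f$V1, start = as.integer(f$V4),
                         end = as.integer(f$V5))
}

#' @rdname read_bed
#' @export
read_linkage_map <- function(path) {
  data.table::as.data.table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_bed
#' @export
read_polarization_table <- function(path) {
  data.table::as.data.table(read.delim(path, stringsAsFactors = FALSE))
}

#' Serialize a model fit to JSON
#'
#' Writes the model family, bounds context (starts, seed), MLEs,
#' log-likelihood and AIC in a structured, human-readable JSON document.
#'
#' @param fit a `"dfe_fit"`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dfe_fit"))
  doc <- list(spec = unclass(fit$spec),
              mle = as.list(natural_params(fit)),
              loglik = fit$loglik, aic = fit$aic,
              n_params = fit$n_params, converged = fit$converged,
              n_starts = fit$n_starts, seed = fit$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
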