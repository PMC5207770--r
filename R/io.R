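# Plain-text readers and writers: beta-matrix TSV (probes x samples),
# probe manifest TSV, sample sheet CSV, dosage TSV, minimal VCF (GT only),
# BED-like local-ancestry tracts, and the simulation-truth JSON record.
# Physical coordinates are 1-based except BED tracts (0-based half-open).

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write / read a beta matrix as probes x samples TSV
#'
#' @param meth A [meth_matrix()].
#' @param path Output path; first column `probe`, then one column per
#'   sample.
#' @export
write_beta_tsv <- function(meth, path) {
  stopifnot(inherits(meth, "meth_matrix"))
  df <- data.frame(probe = meth$probes$probe, t(meth$values),
                   check.names = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_beta_tsv
#' @param manifest Probe manifest data frame (probe, chrom, pos) matching
#'   the file's probes, e.g. from [read_manifest_tsv()].
#' @param scale Scale tag of the stored values.
#' @export
read_beta_tsv <- function(path, manifest, scale = "beta") {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(vals) <- df$probe
  m <- manifest[match(df$probe, manifest$probe), , drop = FALSE]
  meth_matrix(vals, m, scale = scale)
}

#' Write / read the probe manifest (probe, chrom, pos) TSV
#' @param probes Data frame with columns probe, chrom, pos.
#' @param path File path.
#' @export
write_manifest_tsv <- function(probes, path) {
  write_tsv_plain(probes[, c("probe", "chrom", "pos")], path)
}

#' @rdname write_manifest_tsv
#' @export
read_manifest_tsv <- function(path) utils::read.delim(path)

#' Write / read the sample sheet CSV
#' @param sheet Sample sheet data frame.
#' @param path File path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read genotype dosages as TSV
#'
#' Rows are SNPs: columns `snp`, `pos_bp`, `pos_gen`, then one dosage
#' column per sample; missing dosage written as NA.
#'
#' @param geno A [genotype_matrix()].
#' @param path File path.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(geno$snps[, c("snp", "pos_bp", "pos_gen")],
                   t(geno$dosages), check.names = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  dos <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(dos) <- df$snp
  genotype_matrix(dos, df[, c("snp", "pos_bp", "pos_gen")])
}

#' Write genotypes as a minimal VCF (GT only)
#'
#' Phased GT from the haplotype matrix when present (simulated data),
#' otherwise unphased from dosages; missing genotypes written `./.`.
#'
#' @param geno A [genotype_matrix()], optionally carrying the
#'   `"haplotypes"` attribute from [simulate_genotypes()].
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_vcf <- function(geno, path, chrom = "chr1") {
  stopifnot(inherits(geno, "genotype_matrix"))
  haps <- attr(geno, "haplotypes")
  samples <- rownames(geno$dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno$dosages)))
  gt <- if (!is.null(haps)) {
    h1 <- haps[seq(1L, nrow(haps), by = 2L), , drop = FALSE]
    h2 <- haps[seq(2L, nrow(haps), by = 2L), , drop = FALSE]
    matrix(paste0(h1, "|", h2), nrow(geno$dosages))
  } else {
    d <- geno$dosages
    out <- matrix("./.", nrow(d), ncol(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  body <- cbind(chrom, geno$snps$pos_bp, geno$snps$snp, "A", "G", ".",
                "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read GT genotypes from a VCF into a genotype matrix
#'
#' Parses only the GT field; `./.` becomes NA. Genetic positions are
#' reconstructed with the linear 1 cM/Mb map unless `pos_gen` is supplied.
#'
#' @param path VCF path (uncompressed).
#' @param pos_gen Optional genetic positions (Morgans) per variant.
#' @return A [genotype_matrix()].
#' @export
read_vcf_gt <- function(path, pos_gen = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")     # variants x samples
  dos <- matrix(vapply(strsplit(as.vector(gt), "[/|]"), function(a) {
    if (length(a) == 0L || any(a == ".") || anyNA(a)) NA_real_
    else sum(as.numeric(a))
  }, numeric(1)), nrow = nrow(gt))
  dos <- t(dos)
  rownames(dos) <- colnames(gt)
  pos_bp <- as.integer(vcfR::getPOS(v))
  if (is.null(pos_gen)) pos_gen <- bp_to_morgans(pos_bp)
  genotype_matrix(dos, data.frame(snp = vcfR::getID(v), pos_bp = pos_bp,
                                  pos_gen = pos_gen))
}

#' Write / read local-ancestry tracts as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open bp via the 1 cM/Mb map),
#' indiv, hap, ancestry.
#'
#' @param tracts Cohort tract table.
#' @param path File path.
#' @param chrom Chromosome name.
#' @export
write_tracts_bed <- function(tracts, path, chrom = "chr1") {
  df <- data.frame(chrom = chrom,
                   start = as.integer(round(tracts$start * 1e8)),
                   end = as.integer(round(tracts$end * 1e8)),
                   indiv = tracts$indiv, hap = tracts$hap,
                   ancestry = tracts$ancestry)
  write_tsv_plain(df, path)
}

#' @rdname write_tracts_bed
#' @param labels Ancestry labels (recovered from the file if omitted).
#' @export
read_tracts_bed <- function(path, labels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(indiv = df$indiv, hap = df$hap,
                    start = df$start / 1e8, end = df$end / 1e8,
                    ancestry = df$ancestry, stringsAsFactors = FALSE)
  attr(out, "labels") <- if (is.null(labels)) sort(unique(df$ancestry))
                         else labels
  attr(out, "genetic_length") <- max(out$end)
  class(out) <- c("local_ancestry", "data.frame")
  out
}

#' Write the simulation truth record as JSON
#'
#' @param truth A [simulation_truth()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  rec <- list(
    cpgs = truth$cpgs, labels = truth$labels, groups = truth$groups,
    cell_types = truth$cell_types, mu = truth$mu,
    cell_delta = truth$cell_delta, meqtl_snp = truth$meqtl_snp,
    meqtl_beta = truth$meqtl_beta, theta = truth$theta, env = truth$env,
    noise_sd = truth$noise_sd, batch_sd = truth$batch_sd,
    sets = list(meqtl = attr(truth, "meqtl_cpgs"),
                theta = attr(truth, "theta_cpgs"),
                env = attr(truth, "env_cpgs"),
                signature = attr(truth, "signature_cpgs"))
  )
  jsonlite::write_json(rec, path, digits = NA, pretty = TRUE)
}
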