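#' Write a founder panel as VCF plus climate CSV
#'
#' Writes the founder genotypes as a minimal VCF (haploid-coded
#' homozygotes in the GT field: 0, 1, 0/1 for residual heterozygotes,
#' . for missing) and the accession climates of origin plus seed-mix
#' frequencies as a CSV next to it.
#'
#' @param panel a \code{\link{founder_panel}}.
#' @param vcf_path output VCF path (plain text).
#' @param climate_path output CSV path (default: vcf path with
#'   \code{.climate.csv}).
#' @return invisibly, the two paths.
#' @export
write_founder_vcf <- function(panel, vcf_path,
                              climate_path = sub("\\.vcf$", ".climate.csv", vcf_path)) {
  G <- t(panel$genotypes)                 # SNP x accession
  gt <- matrix("1", nrow(G), ncol(G))
  gt[G == 0] <- "0"
  gt[G == 0.5] <- "0/1"
  gt[is.na(G)] <- "."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gardensort",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$accession_ids), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = panel$snp_chrom, POS = panel$snp_pos,
    ID = paste0(panel$snp_chrom, "_", panel$snp_pos),
    REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(hdr, vcf_path)
  data.table::fwrite(body, vcf_path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  clim <- data.table::data.table(accession = panel$accession_ids,
                                 start_freq = panel$start_freq)
  clim <- cbind(clim, data.table::as.data.table(panel$z_origin))
  data.table::fwrite(clim, climate_path)
  invisible(c(vcf = vcf_path, climate = climate_path))
}

#' Read a founder panel from VCF plus climate CSV
#'
#' Reads founder genotypes via \pkg{vcfR} and re-assembles a
#' \code{\link{founder_panel}} together with the accession climate CSV
#' written by \code{\link{write_founder_vcf}}. Only biallelic SNPs are
#' kept.
#'
#' @param vcf_path VCF path.
#' @param climate_path climate CSV path.
#' @return a \code{\link{founder_panel}}.
#' @export
read_founder_vcf <- function(vcf_path,
                             climate_path = sub("\\.vcf$", ".climate.csv", vcf_path)) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfR is required to read VCF files")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  dos[gt %in% c("0", "0|0", "0/0")] <- 0
  dos[gt %in% c("1", "1|1", "1/1")] <- 1
  dos[gt %in% c("0/1", "0|1", "1/0", "1|0")] <- 0.5
  clim <- data.table::fread(climate_path)
  zcols <- setdiff(names(clim), c("accession", "start_freq"))
  founder_panel(t(dos),
                accession_ids = colnames(gt),
                snp_chrom = as.character(v@fix[, "CHROM"]),
                snp_pos = as.integer(v@fix[, "POS"]),
                z_origin = as.matrix(clim[, zcols, with = FALSE]),
                start_freq = clim$start_freq / sum(clim$start_freq))
}

#' Write pooled samples in sync format
#'
#' PoPoolation2-style sync: chrom, pos, ref base, then one
#' \code{A:T:C:G:N:del} column per sample. Ref counts are written as A,
#' alt counts as T (matching the REF/ALT coding of the founder VCF).
#'
#' @param samples list of \code{pool_sample} objects on the same SNP
#'   axis.
#' @param panel the \code{\link{founder_panel}} giving chrom/pos.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_sync <- function(samples, panel, path) {
  cols <- lapply(samples, function(s)
    paste0(s$ref_count, ":", s$alt_count, ":0:0:0:0"))
  dt <- data.table::data.table(chrom = panel$snp_chrom,
                               pos = panel$snp_pos, ref = "A")
  for (i in seq_along(cols)) dt[[paste0("sample", i)]] <- cols[[i]]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read sync-format pooled counts
#'
#' Parses a PoPoolation2-style sync file into per-sample ref/alt counts.
#' Multi-allelic entries are collapsed to ref vs the most common
#' non-reference allele; reads of other alleles are dropped and their
#' total reported as an attribute.
#'
#' @param path sync file path.
#' @return list of \code{pool_sample} objects plus \code{chrom},
#'   \code{pos}; attribute \code{dropped_reads} counts discarded
#'   non-ref non-major-alt reads.
#' @export
read_sync <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  chrom <- as.character(dt[[1]]); pos <- as.integer(dt[[2]])
  ref_base <- toupper(as.character(dt[[3]]))
  bases <- c("A", "T", "C", "G")
  dropped <- 0
  samples <- lapply(seq.int(4, ncol(dt)), function(ci) {
    m <- do.call(rbind, lapply(strsplit(dt[[ci]], ":"), as.integer))
    ref_ix <- match(ref_base, bases)
    ref_cnt <- m[cbind(seq_len(nrow(m)), ref_ix)]
    altm <- m[, 1:4, drop = FALSE]
    altm[cbind(seq_len(nrow(m)), ref_ix)] <- -1L
    alt_ix <- max.col(altm, ties.method = "first")
    alt_cnt <- m[cbind(seq_len(nrow(m)), alt_ix)]
    dropped <<- dropped + sum(m[, 1:4]) - sum(ref_cnt) - sum(alt_cnt) +
      sum(m[, 5:6])
    structure(list(ref_count = ref_cnt, alt_count = alt_cnt,
                   n_flowers = NA_integer_, meta = list()),
              class = "pool_sample")
  })
  out <- list(samples = samples, chrom = chrom, pos = pos)
  attr(out, "dropped_reads") <- dropped
  out
}

#' Write per-sample counts TSV
#'
#' Long-format plain counts: chrom, pos, ref_count, alt_count.
#'
#' @param sample a \code{pool_sample}.
#' @param panel the \code{\link{founder_panel}} for chrom/pos.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_counts_tsv <- function(sample, panel, path) {
  data.table::fwrite(
    data.table::data.table(chrom = panel$snp_chrom, pos = panel$snp_pos,
                           ref_count = sample$ref_count,
                           alt_count = sample$alt_count),
    path, sep = "\t")
  invisible(path)
}

#' Read per-sample counts TSV
#' @param path TSV with columns chrom, pos, ref_count, alt_count.
#' @return a \code{pool_sample}.
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path)
  structure(list(ref_count = dt$ref_count, alt_count = dt$alt_count,
                 n_flowers = NA_integer_, meta = list()),
            class = "pool_sample")
}

#' Write sample metadata CSV
#' @param meta data.frame with sample_id, garden, replicate, generation,
#'   flowers, date.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_metadata_csv <- function(meta, path) {
  data.table::fwrite(meta, path)
  invisible(path)
}

#' Write census CSV
#' @param census data.frame (garden, replicate, generation, census).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_census_csv <- function(census, path) {
  data.table::fwrite(census, path)
  invisible(path)
}

#' Write a frequency table as long TSV
#' @param freqs a \code{freq_table}.
#' @param panel the \code{\link{founder_panel}}.
#' @param sample_id sample label.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_freq_tsv <- function(freqs, panel, sample_id, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = sample_id, chrom = panel$snp_chrom,
                           pos = panel$snp_pos, freq = freqs$freq,
                           depth = if (is.null(freqs$depth)) NA else freqs$depth),
    path, sep = "\t")
  invisible(path)
}

#' Write accession frequencies as long TSV
#' @param accfreq an \code{acc_freq}.
#' @param sample_id sample label.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_accfreq_tsv <- function(accfreq, sample_id, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = sample_id,
                           accession_id = names(accfreq$freq),
                           freq = as.numeric(accfreq$freq)),
    path, sep = "\t")
  invisible(path)
}
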