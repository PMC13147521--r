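# SNP panel selection from parental genotypes and the per-sample exclusion
# rules. Filters never alter read counts: per-sample rules set a logical
# `masked` column (with a reason), panel-level rules drop a SNP for every
# sample the same way, so conservation is checkable by row identity.

GT_LEVELS <- c("hom_ref", "hom_alt", "het", "missing")

#' Construct a parental-genotype table
#'
#' @param df data.frame with columns `stock`, `chrom`, `pos`, `gt`
#'   (one of `"hom_ref"`, `"hom_alt"`, `"het"`, `"missing"`) and optionally
#'   `is_indel` (logical; defaults to FALSE).
#' @return Validated data.frame of class `parental_genotypes`.
#' @export
parental_genotypes <- function(df) {
  stopifnot(all(c("stock", "chrom", "pos", "gt") %in% names(df)))
  if (!all(df$gt %in% GT_LEVELS)) {
    stop("gt must be one of: ", paste(GT_LEVELS, collapse = ", "))
  }
  if (is.null(df$is_indel)) df$is_indel <- FALSE
  if (anyDuplicated(df[c("stock", "chrom", "pos")])) {
    stop("one record per (stock, chrom, pos) required")
  }
  structure(df, class = c("parental_genotypes", "data.frame"))
}

#' Select SNPs informative between the two parental stocks
#'
#' Keeps SNPs that are homozygous in both parental stocks and different
#' between them (biallelic between the two parental genotypes); drops indels
#' and sites with missing or heterozygous calls in either stock.
#'
#' @param parents A [parental_genotypes()] table.
#' @param p1,p2 Stock labels of the two parents.
#' @return data.frame with columns `chrom`, `pos`, `p1_gt`, `p2_gt` — the SNP
#'   panel.
#' @export
select_informative_snps <- function(parents, p1 = "P1", p2 = "P2") {
  g1 <- parents[parents$stock == p1 & !parents$is_indel, c("chrom", "pos", "gt")]
  g2 <- parents[parents$stock == p2 & !parents$is_indel, c("chrom", "pos", "gt")]
  m <- merge(g1, g2, by = c("chrom", "pos"), suffixes = c("_p1", "_p2"))
  if (nrow(m) == 0) stop("no SNPs shared between the two parental stocks")
  hom <- c("hom_ref", "hom_alt")
  keep <- m$gt_p1 %in% hom & m$gt_p2 %in% hom & m$gt_p1 != m$gt_p2
  out <- m[keep, ]
  names(out) <- c("chrom", "pos", "p1_gt", "p2_gt")
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Remove third-stock SNPs from non-focal chromosomes
#'
#' On the chromosomes listed in `chroms` (by default X and 3, where the
#' compound-chromosome father contributes sequence), SNPs whose variant
#' allele is also present in the third stock (heterozygous or homozygous
#' alt) are disregarded. Focal-chromosome SNPs are untouched.
#'
#' @param panel SNP panel from [select_informative_snps()].
#' @param parents A [parental_genotypes()] table containing the third stock.
#' @param stock_c Label of the third stock.
#' @param chroms Chromosome labels the rule applies to.
#' @return The filtered panel.
#' @export
exclude_third_stock_snps <- function(panel, parents, stock_c = "C",
                                     chroms = c("X", "3L", "3R", "3")) {
  gc <- parents[parents$stock == stock_c, c("chrom", "pos", "gt")]
  m <- merge(panel, gc, by = c("chrom", "pos"), all.x = TRUE)
  m$gt[is.na(m$gt)] <- "missing"
  drop <- m$chrom %in% chroms & m$gt %in% c("het", "hom_alt")
  out <- m[!drop, setdiff(names(m), "gt")]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Construct a counts matrix
#'
#' The pipeline's central observable: per-sample, per-SNP reference and
#' alternate read counts, with a derived alt-allele frequency and a `masked`
#' flag manipulated by the filters.
#'
#' @param df data.frame with columns `sample`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`.
#' @return data.frame of class `counts_matrix` with added columns `depth`,
#'   `freq` (NA where depth is 0), `masked`, `mask_reason`.
#' @export
counts_matrix <- function(df) {
  stopifnot(all(c("sample", "chrom", "pos", "ref_count", "alt_count") %in% names(df)))
  if (any(df$ref_count < 0 | df$alt_count < 0)) stop("negative read counts")
  df$depth <- df$ref_count + df$alt_count
  df$freq <- ifelse(df$depth > 0, df$alt_count / df$depth, NA_real_)
  if (is.null(df$masked)) df$masked <- rep(FALSE, nrow(df))
  if (is.null(df$mask_reason)) df$mask_reason <- rep(NA_character_, nrow(df))
  class(df) <- c("counts_matrix", "data.frame")
  df
}

#' Mask low-depth observations
#'
#' Masks each (sample, SNP) observation whose sequencing depth is below
#' `min_depth` (default 8 reads). Per-sample, per-SNP: other samples keep
#' the SNP.
#'
#' @param counts A [counts_matrix()].
#' @param min_depth Minimum depth to keep an observation.
#' @return The counts matrix with `masked` updated.
#' @export
apply_depth_filter <- function(counts, min_depth = 8) {
  stopifnot(min_depth >= 1)
  hit <- !counts$masked & counts$depth < min_depth
  counts$masked[hit] <- TRUE
  counts$mask_reason[hit] <- "low_depth"
  counts
}

#' Drop SNPs with low allele-frequency variance across the cohort
#'
#' Computes, for every SNP, the population variance (divide-by-n) of the
#' alt-allele frequency over the samples with unmasked observations, and
#' masks the SNP for all samples when the variance is below `min_var`
#' (default 0.01). SNPs evaluable in fewer than two samples are retained
#' with a warning.
#'
#' @param counts A [counts_matrix()] (depth filtering should run first).
#' @param min_var Variance threshold.
#' @return The counts matrix with `masked` updated.
#' @export
apply_variance_filter <- function(counts, min_var = 0.01) {
  stopifnot(min_var >= 0)
  key <- paste(counts$chrom, counts$pos)
  ok <- !counts$masked & !is.na(counts$freq)
  n_ok <- tapply(ok, key, sum)
  pop_var <- rep(NA_real_, length(n_ok))
  names(pop_var) <- names(n_ok)
  evaluable <- names(n_ok)[n_ok >= 2]
  if (length(evaluable)) {
    f <- counts$freq[ok]
    k <- key[ok]
    mu <- tapply(f, k, mean)
    ss <- tapply(f^2, k, mean)
    pv <- ss - mu^2
    pop_var[names(pv)] <- pv
  }
  few <- names(n_ok)[n_ok < 2]
  if (length(few)) {
    warning(sprintf("%d SNP(s) evaluable in <2 samples; retained unfiltered",
                    length(few)))
  }
  low <- names(pop_var)[!is.na(pop_var) & pop_var < min_var &
                          names(pop_var) %in% evaluable]
  hit <- key %in% low & !counts$masked
  counts$masked[hit] <- TRUE
  counts$mask_reason[hit] <- "low_variance"
  counts
}

#' Summarize filtering between two states of a counts matrix
#'
#' @param before,after Counts matrices before and after filtering (same rows).
#' @return List with `per_sample` (data.frame: sample, n_total,
#'   n_unmasked_before, n_unmasked_after, n_low_depth, n_low_variance) and
#'   `panel` (SNP-level counts before/after).
#' @export
filter_report <- function(before, after) {
  stopifnot(nrow(before) == nrow(after),
            all(before$sample == after$sample),
            all(before$pos == after$pos))
  samples <- unique(after$sample)
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    i <- after$sample == s
    data.frame(
      sample = s,
      n_total = sum(i),
      n_unmasked_before = sum(i & !before$masked),
      n_unmasked_after = sum(i & !after$masked),
      n_low_depth = sum(i & after$masked &
                          after$mask_reason %in% "low_depth", na.rm = TRUE),
      n_low_variance = sum(i & after$masked &
                             after$mask_reason %in% "low_variance", na.rm = TRUE)
    )
  }))
  snp_key <- function(m) unique(paste(m$chrom, m$pos)[!m$masked])
  list(
    per_sample = per_sample,
    panel = data.frame(
      n_snps_before = length(snp_key(before)),
      n_snps_after = length(snp_key(after))
    )
  )
}

#' Flag samples with insufficient panel coverage
#'
#' A sample is flagged when the fraction of panel SNPs it covers at depth
#' `min_depth` or more falls below `min_fraction`. Mirrors the by-eye
#' exclusion of low-coverage individuals; the threshold is a declared
#' configuration value, not tuned.
#'
#' @param counts A [counts_matrix()].
#' @param min_fraction Minimum fraction of SNPs adequately covered.
#' @param min_depth Depth defining "covered".
#' @return data.frame: `sample`, `covered_fraction`, `excluded`.
#' @export
flag_low_coverage_samples <- function(counts, min_fraction = 0.5, min_depth = 8) {
  samples <- unique(counts$sample)
  frac <- vapply(samples, function(s) {
    i <- counts$sample == s
    mean(counts$depth[i] >= min_depth)
  }, 0)
  data.frame(sample = samples, covered_fraction = frac,
             excluded = frac < min_fraction, row.names = NULL)
}

# --- VCF readers (vcfR-backed) ---------------------------------------------

require_vcfR <- function() {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
}

#' Read per-sample read counts from a VCF with AD fields
#'
#' Uses the AD (allele depth) FORMAT field of a multi-sample VCF; indel
#' records are dropped.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A [counts_matrix()] in long format.
#' @export
read_counts_vcf <- function(path) {
  require_vcfR()
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 & !grepl(",", fix[, "ALT"])
  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- ad[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  parse_ad <- function(x, field) {
    out <- suppressWarnings(as.integer(vapply(strsplit(x, ","), function(p) {
      if (length(p) >= field) p[field] else NA_character_
    }, "")))
    out[is.na(out)] <- 0L
    out
  }
  rows <- lapply(colnames(ad), function(s) {
    data.frame(sample = s, chrom = fix[, "CHROM"],
               pos = as.numeric(fix[, "POS"]),
               ref_count = parse_ad(ad[, s], 1L),
               alt_count = parse_ad(ad[, s], 2L))
  })
  counts_matrix(do.call(rbind, rows))
}

#' Read stock genotypes from a VCF
#'
#' Converts GT calls of each sample into the categorical genotypes used by
#' [parental_genotypes()]; records with symbolic or multi-allelic ALT are
#' dropped, indels flagged.
#'
#' @param path VCF file.
#' @return A [parental_genotypes()] table (stock = VCF sample name).
#' @export
read_parental_vcf <- function(path) {
  require_vcfR()
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ok <- !grepl(",", fix[, "ALT"])
  fix <- fix[ok, , drop = FALSE]
  gt <- gt[ok, , drop = FALSE]
  is_indel <- nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep("missing", length(g))
    out[g %in% c("0/0")] <- "hom_ref"
    out[g %in% c("1/1")] <- "hom_alt"
    out[g %in% c("0/1", "1/0")] <- "het"
    out
  }
  rows <- lapply(colnames(gt), function(s) {
    data.frame(stock = s, chrom = fix[, "CHROM"],
               pos = as.numeric(fix[, "POS"]),
               gt = code(gt[, s]), is_indel = is_indel)
  })
  parental_genotypes(do.call(rbind, rows))
}
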