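# VCF input/output. Reading goes through vcfR; writing uses a minimal
# VCF 4.2 text writer (GT-only for SNPs; SVTYPE/SVLEN/END INFO keys for SVs).
# Internal positions are 0-based; VCF POS is 1-based and converted on the way
# in/out.

.gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

.format_gt <- function(g) {
  out <- rep("./.", length(g))
  ok <- !is.na(g)
  out[ok] <- .gt_strings[as.character(g[ok])]
  out
}

.vcf_header <- function(layout, extra = character(), samples) {
  c("##fileformat=VCFv4.2",
    "##source=recdiv",
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom, as.integer(layout$length)),
    extra,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write biallelic SNP genotypes to VCF 4.2
#'
#' @param chrom,pos SNP coordinates (`pos` 0-based; written as POS = pos + 1).
#' @param gt list of per-population genotype matrices (SNPs x individuals;
#'   dosages 0/1/2, NA = missing). Population names become sample prefixes.
#' @param layout a [genome_layout()] (for `##contig` lines).
#' @param path output path.
#' @export
write_snp_vcf <- function(chrom, pos, gt, layout, path) {
  stopifnot(is.list(gt), length(gt) >= 1)
  pops <- names(gt)
  if (is.null(pops)) pops <- paste0("pop", seq_along(gt))
  samples <- unlist(lapply(seq_along(gt), function(i) {
    paste0(pops[i], "_", seq_len(ncol(gt[[i]])))
  }))
  gall <- do.call(cbind, gt)
  n <- length(chrom)
  stopifnot(nrow(gall) == n, length(pos) == n)
  gtxt <- apply(gall, 1L, function(row) paste(.format_gt(row), collapse = "\t"))
  body <- paste(chrom, as.integer(pos) + 1L, paste0("snp", seq_len(n)),
                "A", "T", ".", "PASS", ".", "GT", gtxt, sep = "\t")
  writeLines(c(.vcf_header(layout, samples = samples), body), path)
  invisible(path)
}

.dosage_from_gt <- function(gtmat) {
  d <- matrix(NA_integer_, nrow(gtmat), ncol(gtmat))
  gg <- substr(gsub("\\|", "/", gtmat), 1, 3)
  d[gg == "0/0"] <- 0L
  d[gg %in% c("0/1", "1/0")] <- 1L
  d[gg == "1/1"] <- 2L
  d
}

#' Read a biallelic SNP VCF into a per-SNP count table
#'
#' Parses with vcfR and summarizes genotypes into the per-population counts
#' the F_ST machinery needs. Samples are assigned to populations either by
#' `pop_map` (named vector sample -> population) or by the `<pop>_<i>` prefix
#' convention of [write_snp_vcf()].
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pop_map optional named character vector mapping sample names to
#'   population labels; if `NULL`, the prefix before the last underscore.
#' @return a `snp_table`: `data.table` with `chrom`, `pos` (0-based), and per
#'   population `n` (genotyped diploids), `ac` (alt allele count), `het`
#'   (heterozygote count), suffixed `1`/`2` in population order.
#' @export
read_snp_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gtm <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gtm)
  if (is.null(pop_map)) {
    pops <- sub("_[^_]*$", "", samples)
  } else {
    pops <- unname(pop_map[samples])
  }
  upop <- unique(pops)
  if (length(upop) != 2L) stop("expected exactly 2 populations, got: ",
                               paste(upop, collapse = ", "))
  d <- .dosage_from_gt(gtm)
  counts <- lapply(upop, function(p) {
    dd <- d[, pops == p, drop = FALSE]
    list(n = rowSums(!is.na(dd)),
         ac = rowSums(dd, na.rm = TRUE),
         het = rowSums(dd == 1L, na.rm = TRUE))
  })
  snp_table(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]) - 1,
            n1 = counts[[1]]$n, ac1 = counts[[1]]$ac, het1 = counts[[1]]$het,
            n2 = counts[[2]]$n, ac2 = counts[[2]]$ac, het2 = counts[[2]]$het,
            populations = upop)
}

#' Construct a per-SNP genotype-count table
#'
#' @param chrom,pos SNP coordinates (0-based).
#' @param n1,ac1,het1 population 1: genotyped diploid count, alt allele
#'   count, heterozygote count.
#' @param n2,ac2,het2 same for population 2.
#' @param populations length-2 character vector of population labels.
#' @return `snp_table` data.table, sorted by position.
#' @export
snp_table <- function(chrom, pos, n1, ac1, het1, n2, ac2, het2,
                      populations = c("pop1", "pop2")) {
  x <- data.table(chrom = as.character(chrom), pos = as.numeric(pos),
                  n1 = as.numeric(n1), ac1 = as.numeric(ac1), het1 = as.numeric(het1),
                  n2 = as.numeric(n2), ac2 = as.numeric(ac2), het2 = as.numeric(het2))
  if (any(x$ac1 > 2 * x$n1) || any(x$ac2 > 2 * x$n2)) {
    stop("allele counts exceed 2 * sample size")
  }
  if (any(x$het1 > x$n1) || any(x$het2 > x$n2)) stop("het counts exceed sample size")
  setorder(x, chrom, pos)
  setattr(x, "populations", populations)
  x[]
}

#' Write a structural-variant catalogue to VCF 4.2
#'
#' @param sv an `sv_table` (see [sv_table()]).
#' @param gt optional list of per-population genotype matrices as in
#'   [write_snp_vcf()]; if omitted a site-only VCF is written.
#' @param layout a [genome_layout()].
#' @param path output path.
#' @export
write_sv_vcf <- function(sv, layout, path, gt = NULL) {
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", sv$type,
                  ifelse(sv$type == "DEL", -as.integer(sv$length_bp),
                         as.integer(sv$length_bp)),
                  as.integer(sv$pos + ifelse(sv$type == "INS", 1L, sv$length_bp)))
  alt <- paste0("<", sv$type, ">")
  extra <- c('##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
             '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
             '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">')
  if (is.null(gt)) {
    hdr <- c("##fileformat=VCFv4.2", "##source=recdiv",
             sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                     as.integer(layout$length)),
             extra,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
    body <- paste(sv$chrom, as.integer(sv$pos) + 1L, sv$sv_id, "N", alt, ".",
                  "PASS", info, sep = "\t")
  } else {
    pops <- names(gt)
    samples <- unlist(lapply(seq_along(gt), function(i) {
      paste0(pops[i], "_", seq_len(ncol(gt[[i]])))
    }))
    hdr <- .vcf_header(layout, extra, samples)
    gall <- do.call(cbind, gt)
    gtxt <- apply(gall, 1L, function(row) paste(.format_gt(row), collapse = "\t"))
    body <- paste(sv$chrom, as.integer(sv$pos) + 1L, sv$sv_id, "N", alt, ".",
                  "PASS", info, "GT", gtxt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a structural-variant VCF
#'
#' Accepts VCFs with `SVTYPE` in {DEL, INS, INV} and `SVLEN` INFO keys.
#' Records with unknown SVTYPE are rejected with a warning. If genotypes are
#' present, per-population counts are extracted as in [read_snp_vcf()].
#'
#' @inheritParams read_snp_vcf
#' @return an `sv_table`.
#' @export
read_sv_vcf <- function(path, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info <- fix[, "INFO"]
  svtype <- sub(".*SVTYPE=([^;]+).*", "\\1", info)
  svlen <- abs(as.numeric(sub(".*SVLEN=(-?[0-9]+).*", "\\1", info)))
  keep <- svtype %in% c("DEL", "INS", "INV")
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with unknown SVTYPE rejected")
  }
  id <- fix[, "ID"]
  if (all(is.na(id))) id <- paste0("sv", seq_along(svtype))
  has_gt <- nrow(v@gt %||% matrix(nrow = 0, ncol = 0)) > 0
  if (has_gt) {
    gtm <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gtm)
    pops <- if (is.null(pop_map)) sub("_[^_]*$", "", samples) else unname(pop_map[samples])
    upop <- unique(pops)
    d <- .dosage_from_gt(gtm)
    cnt <- lapply(upop, function(p) {
      dd <- d[, pops == p, drop = FALSE]
      list(n = rowSums(!is.na(dd)), ac = rowSums(dd, na.rm = TRUE),
           het = rowSums(dd == 1L, na.rm = TRUE))
    })
    out <- sv_table(sv_id = id, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]) - 1,
                    type = svtype, length_bp = svlen,
                    n1 = cnt[[1]]$n, ac1 = cnt[[1]]$ac, het1 = cnt[[1]]$het,
                    n2 = cnt[[2]]$n, ac2 = cnt[[2]]$ac, het2 = cnt[[2]]$het)
  } else {
    out <- sv_table(sv_id = id, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]) - 1,
                    type = svtype, length_bp = svlen)
  }
  out[keep[match(out$sv_id, id)]][]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a structural-variant table
#'
#' @param sv_id record identifiers.
#' @param chrom,pos coordinates (`pos` 0-based anchor).
#' @param type SV type, each of `DEL`, `INS`, `INV`.
#' @param length_bp SV length (> 0).
#' @param n1,ac1,het1,n2,ac2,het2 optional per-population genotype counts
#'   (as in [snp_table()]), treating SV presence/absence as a biallelic locus.
#' @return `sv_table` data.table with derived `af1`, `af2` (alt frequencies)
#'   and `size_class` (`small` < 1 kb, `large` >= 1 kb).
#' @export
sv_table <- function(sv_id, chrom, pos, type, length_bp,
                     n1 = NULL, ac1 = NULL, het1 = NULL,
                     n2 = NULL, ac2 = NULL, het2 = NULL) {
  if (!all(type %in% c("DEL", "INS", "INV"))) stop("type must be DEL, INS or INV")
  if (any(length_bp <= 0)) stop("SV lengths must be > 0")
  x <- data.table(sv_id = as.character(sv_id), chrom = as.character(chrom),
                  pos = as.numeric(pos), type = type,
                  length_bp = as.numeric(length_bp))
  if (!is.null(n1)) {
    x[, `:=`(n1 = as.numeric(n1), ac1 = as.numeric(ac1), het1 = as.numeric(het1),
             n2 = as.numeric(n2), ac2 = as.numeric(ac2), het2 = as.numeric(het2))]
    x[, `:=`(af1 = ac1 / (2 * n1), af2 = ac2 / (2 * n2))]
  }
  x[, size_class := ifelse(length_bp >= 1000, "large", "small")]
  setorder(x, chrom, pos)
  x[]
}

#' Reference span of structural variants
#'
#' DEL occupies `[pos, pos + len)`; INS is anchored at a 1 bp reference span
#' `[pos, pos + 1)` (inserted sequence absent from the reference); INV spans
#' `[pos, pos + len)`.
#'
#' @param sv an `sv_table`.
#' @return region set with `label` = `sv_id`.
#' @export
sv_spans <- function(sv) {
  len <- ifelse(sv$type == "INS", 1, sv$length_bp)
  regions(sv$chrom, sv$pos, sv$pos + len, label = sv$sv_id)
}
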