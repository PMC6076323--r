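#' Construct a marker dosage matrix
#'
#' A `marker_matrix` wraps a lines-by-markers matrix of alternate-allele
#' dosages (0/1/2, `NA` for missing) together with a platform tag. Platform
#' labels follow the study convention: `G1` for the high-density GBS panel,
#' `G2` for the lower-density DArTseq panel and `G3` for the combined panel.
#'
#' @param dosages Numeric matrix, lines in rows (rownames = line IDs),
#'   markers in columns (colnames = marker IDs). Entries 0, 1, 2 or `NA`
#'   (fractional dosages are allowed after imputation).
#' @param platform Character platform tag.
#' @param imputed Logical; `TRUE` once missing values have been imputed
#'   (entries may then be fractional).
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(dosages, platform = "G1", imputed = FALSE) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("L", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages)) > 0) abort("Duplicate line identifiers.")
  if (anyDuplicated(colnames(dosages)) > 0) abort("Duplicate marker identifiers.")
  vals <- dosages[!is.na(dosages)]
  if (!imputed && length(vals) > 0 && !all(vals %in% c(0, 1, 2))) {
    abort("Dosage entries must be 0, 1, 2 or NA.")
  }
  if (imputed && length(vals) > 0 && (min(vals) < 0 || max(vals) > 2)) {
    abort("Imputed dosages must lie in [0, 2].")
  }
  structure(
    list(dosages = dosages, platform = platform, imputed = imputed),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf(
    "<marker_matrix> platform %s: %d lines x %d markers (%.1f%% missing%s)\n",
    x$platform, nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages)), if (x$imputed) ", imputed" else ""
  ))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

#' Line identifiers of a marker matrix or genomic relationship
#' @param x A `marker_matrix` or `genomic_relationship`.
#' @return Character vector of line IDs.
#' @export
lines_of <- function(x) {
  if (inherits(x, "marker_matrix")) return(rownames(x$dosages))
  if (inherits(x, "genomic_relationship")) return(x$lines)
  abort("`x` must be a marker_matrix or genomic_relationship.")
}

#' Read SNP genotypes as alternate-allele dosages
#'
#' Reads either a VCF (v4.x) or a plain tab-delimited dosage matrix (first
#' column line ID, header row of marker IDs, `NA` for missing). VCF sites are
#' encoded as the count of the first alternate allele; multi-allelic sites
#' are skipped and their number reported via message and the
#' `"n_multiallelic"` attribute. Marker IDs for VCF input are `chrom:pos`
#' (1-based coordinates preserved).
#'
#' @param path Path to the genotype file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param platform Platform tag attached to the result.
#' @return A [marker_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           platform = "G1") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "dosage"
    }
  }
  if (format == "vcf") .read_vcf_dosages(path, platform) else {
    .read_dosage_matrix(path, platform)
  }
}

.read_vcf_dosages <- function(path, platform) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    inform(sprintf("Skipping %d multi-allelic site(s).", n_multi))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(gt), colnames(gt)))
  keep <- !multi
  if (sum(keep) == 0) abort("No biallelic sites in VCF.")
  gt <- gt[keep, , drop = FALSE]
  ids <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])
  # dosage = count of alternate alleles in the GT field
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  })
  dose <- t(dose)  # lines x markers
  colnames(dose) <- ids
  out <- marker_matrix(dose, platform = platform)
  attr(out, "n_multiallelic") <- n_multi
  out
}

.read_dosage_matrix <- function(path, platform) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("Dosage matrix needs a line-ID column plus markers.")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  marker_matrix(m, platform = platform)
}

#' Write a marker matrix as a tab-delimited dosage file
#' @param m A [marker_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- tibble::as_tibble(m$dosages, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(line = rownames(m$dosages)), df)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a marker matrix as a minimal biallelic VCF
#'
#' Dosages 0/1/2 map to genotypes `0/0`, `0/1`, `1/1`; missing to `./.`.
#' Marker IDs of the form `chrom:pos` are split back into CHROM/POS;
#' otherwise markers are placed on a single pseudo-chromosome in order.
#'
#' @param m A [marker_matrix()] with integer (non-imputed) dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$imputed) abort("Cannot write imputed (fractional) dosages as VCF.")
  ids <- colnames(m$dosages)
  if (all(grepl("^[^:]+:[0-9]+$", ids))) {
    chrom <- sub(":.*$", "", ids)
    pos <- sub("^.*:", "", ids)
  } else {
    chrom <- rep("1", length(ids))
    pos <- as.character(seq_along(ids))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gm <- m$dosages
  gt <- matrix("./.", nrow = ncol(gm), ncol = nrow(gm))
  for (i in seq_len(ncol(gm))) {
    g <- gm[, i]
    gt[i, ] <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t")
  )
  body <- vapply(seq_along(ids), function(i) {
    paste(c(chrom[i], pos[i], ids[i], "A", "T", ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter markers on missingness and allele frequency, and mean-impute
#'
#' Markers with a missing-call fraction above `max_missing`, a minor allele
#' frequency (computed on non-missing calls) below `min_maf`, or no
#' polymorphism at all are removed; remaining missing dosages are replaced by
#' the marker's mean dosage. The operation is idempotent.
#'
#' @param m A [marker_matrix()].
#' @param max_missing Maximum tolerated fraction of missing calls per marker.
#' @param min_maf Minimum minor allele frequency per marker.
#' @return A [marker_matrix()] with no missing entries (`imputed = TRUE`).
#' @export
filter_and_impute <- function(m, max_missing = 0.2, min_maf = 0.01) {
  stopifnot(inherits(m, "marker_matrix"))
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1) {
    abort("Thresholds must lie in [0, 1].")
  }
  x <- m$dosages
  miss <- colMeans(is.na(x))
  p_alt <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  # a marker with every call missing or identical carries no information
  nvar <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    length(v) > 0 && length(unique(v)) > 1
  })
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf & nvar
  if (!any(keep)) {
    abort("All markers removed by QC: empty marker panel.")
  }
  x <- x[, keep, drop = FALSE]
  cm <- colMeans(x, na.rm = TRUE)
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx) > 0) x[na_idx] <- cm[na_idx[, 2]]
  marker_matrix(x, platform = m$platform, imputed = TRUE)
}

#' Polymorphism information content of a biallelic marker
#'
#' For allele frequency p (q = 1 - p), PIC = 1 - p^2 - q^2 - 2 p^2 q^2.
#' The maximum, 0.375, occurs at p = 0.5.
#'
#' @param allele_freq Numeric vector of allele frequencies in \[0, 1\].
#' @return Numeric vector of PIC scores.
#' @export
#' @examples
#' compute_pic(0.5)  # 0.375
compute_pic <- function(allele_freq) {
  if (any(is.na(allele_freq)) || any(allele_freq < 0 | allele_freq > 1)) {
    abort("Allele frequencies must lie in [0, 1].")
  }
  p <- allele_freq
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

#' Combine two marker platforms into one panel
#'
#' Column-concatenates two (typically QC-filtered) marker panels over their
#' common lines; marker identifiers are disambiguated with a platform suffix
#' and the result is tagged `G3`.
#'
#' @param m1,m2 Two [marker_matrix()] objects.
#' @param platform Platform tag for the combined panel.
#' @return A [marker_matrix()] over the intersection of the line sets.
#' @export
combine_platforms <- function(m1, m2, platform = "G3") {
  stopifnot(inherits(m1, "marker_matrix"), inherits(m2, "marker_matrix"))
  common <- intersect(rownames(m1$dosages), rownames(m2$dosages))
  if (length(common) == 0) abort("Line sets of the two panels are disjoint.")
  if (length(common) < nrow(m1$dosages) || length(common) < nrow(m2$dosages)) {
    warn(sprintf(
      "Line sets differ; keeping the %d common lines.", length(common)
    ))
  }
  x1 <- m1$dosages[common, , drop = FALSE]
  x2 <- m2$dosages[common, , drop = FALSE]
  colnames(x1) <- paste0(colnames(x1), ".", m1$platform)
  colnames(x2) <- paste0(colnames(x2), ".", m2$platform)
  marker_matrix(cbind(x1, x2), platform = platform,
                imputed = m1$imputed || m2$imputed)
}
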