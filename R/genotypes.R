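#' Construct a genotype-matrix object from minor-allele dosages
#'
#' The basic genotype container used throughout towge: an `n x m` matrix of
#' minor-allele counts (0/1/2) for `n` individuals and `m` variants in one
#' testing region (a gene or pathway), together with per-variant sample minor
#' allele frequencies (MAFs).
#'
#' Ingest cleaning applies, in order: (1) per-variant mean imputation of
#' missing dosages (imputed entries lie in `[0, 2]` but need not be integer);
#' (2) allele folding -- if the allele frequency of the coded allele exceeds
#' 0.5 the coding is flipped (`dosage <- 2 - dosage`) so that the coded allele
#' is always the minor allele on the analyzed sample, and the flip is flagged;
#' (3) MAF computation as `sum(dosages[, j]) / (2 * n)`.
#'
#' @param dosages numeric matrix (individuals in rows, variants in columns) of
#'   allele counts in `{0, 1, 2}`; `NA` allowed and mean-imputed. A data frame
#'   whose first column is an individual id is also accepted.
#' @param variant_ids character vector of variant labels; defaults to the
#'   column names of `dosages`.
#' @returns an object of class `ge_genotypes` with elements `dosages`,
#'   `variant_id`, `maf`, `flipped` (logical, per variant), `n_imputed`
#'   (count of imputed entries per variant).
#' @examples
#' g <- ge_genotypes(cbind(v1 = c(0, 1, 2), v2 = c(0, 0, 1)))
#' g$maf
#' @export
ge_genotypes <- function(dosages, variant_ids = NULL) {
  if (is.data.frame(dosages)) {
    first_chr <- !is.numeric(dosages[[1]])
    ids <- if (first_chr) as.character(dosages[[1]]) else NULL
    dosages <- as.matrix(if (first_chr) dosages[-1] else dosages)
    if (!is.null(ids)) rownames(dosages) <- ids
  }
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    stop("`dosages` must be a numeric matrix or a data frame of dosages.")
  }
  if (ncol(dosages) < 1L || nrow(dosages) < 1L) {
    stop("`dosages` must have at least one individual and one variant.")
  }
  if (is.null(variant_ids)) variant_ids <- colnames(dosages)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(dosages)))
  stopifnot(length(variant_ids) == ncol(dosages))

  bad <- !is.na(dosages) & !(dosages >= 0 & dosages <= 2)
  if (any(bad)) stop("dosages must lie in [0, 2] (minor-allele counts).")

  n_imputed <- integer(ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (all(miss)) stop("variant ", variant_ids[j], " has no observed genotypes.")
    if (any(miss)) {
      dosages[miss, j] <- mean(dosages[!miss, j])
      n_imputed[j] <- sum(miss)
    }
  }

  raw_af <- colSums(dosages) / (2 * nrow(dosages))
  flipped <- raw_af > 0.5
  if (any(flipped)) {
    dosages[, flipped] <- 2 - dosages[, flipped]
  }
  maf <- colSums(dosages) / (2 * nrow(dosages))
  colnames(dosages) <- variant_ids

  structure(
    list(dosages = dosages, variant_id = variant_ids, maf = unname(maf),
         flipped = unname(flipped), n_imputed = n_imputed),
    class = "ge_genotypes"
  )
}

#' @export
print.ge_genotypes <- function(x, ...) {
  cat(sprintf("<ge_genotypes> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range [%.4g, %.4g]; %d flipped coding(s); %d imputed entr%s\n",
              min(x$maf), max(x$maf), sum(x$flipped), sum(x$n_imputed),
              if (sum(x$n_imputed) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
dim.ge_genotypes <- function(x) dim(x$dosages)

#' Tidy per-variant summary of a genotype object
#'
#' @param x a [ge_genotypes] object.
#' @param ... unused.
#' @returns a tibble with one row per variant: `variant_id`, `maf`,
#'   `flipped`, `n_imputed`.
#' @method tidy ge_genotypes
#' @export
tidy.ge_genotypes <- function(x, ...) {
  tibble::tibble(variant_id = x$variant_id, maf = x$maf,
                 flipped = x$flipped, n_imputed = x$n_imputed)
}

#' Read region genotypes from a VCF or a plain dosage table
#'
#' Accepts either a VCF (v4.x, parsed with \pkg{vcfR}) or a TSV dosage table
#' whose header row holds variant ids and whose first column is an individual
#' id. VCF genotypes are converted to ALT-allele counts and then folded to the
#' sample minor allele by [ge_genotypes()]. Multi-allelic VCF records are
#' rejected by default; with `multiallelic = "split"` each ALT allele becomes
#' its own pseudo-variant (id suffixed `_<k>`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"table"`.
#' @param multiallelic `"reject"` (default) or `"split"`.
#' @returns a [ge_genotypes] object; individuals in rows, named when ids are
#'   available.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "table"),
                           multiallelic = c("reject", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "table"
  }
  if (format == "table") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(ge_genotypes(tab))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  ids <- vcfR::getID(vcf)
  ids[is.na(ids)] <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))[is.na(ids)]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(alt), dimnames = list(NULL, names(gt)))

  multi <- grepl(",", alt)
  if (any(multi) && multiallelic == "reject") {
    stop("multi-allelic record(s) at ", paste(ids[multi], collapse = ", "),
         "; re-run with multiallelic = \"split\" to expand them.")
  }

  count_allele <- function(gt_row, k) {
    # gt strings like 0/1, 1|2, ./.; count occurrences of allele k
    vapply(strsplit(gt_row, "[/|]"), function(a) {
      if (all(a == "." | is.na(a))) return(NA_real_)
      sum(a == as.character(k))
    }, numeric(1))
  }

  cols <- list(); cids <- character(0)
  for (r in seq_along(ids)) {
    n_alt <- length(strsplit(alt[r], ",")[[1]])
    for (k in seq_len(n_alt)) {
      cols[[length(cols) + 1L]] <- count_allele(gt[r, ], k)
      cids <- c(cids, if (n_alt == 1) ids[r] else paste0(ids[r], "_", k))
    }
  }
  dos <- do.call(cbind, cols)
  colnames(dos) <- cids
  rownames(dos) <- colnames(gt)
  ge_genotypes(dos)
}

#' Write a genotype object as a plain dosage table
#'
#' Round-trips exactly with [read_genotypes()] (table format): header of
#' variant ids, first column `sample`.
#'
#' @param g a [ge_genotypes] object.
#' @param path output TSV path.
#' @returns `path`, invisibly.
#' @export
write_dosage_table <- function(g, path) {
  df <- tibble::as_tibble(g$dosages)
  sample_id <- rownames(g$dosages)
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(g$dosages)))
  df <- dplyr::bind_cols(tibble::tibble(sample = sample_id), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Partition variants into rare and common by sample MAF
#'
#' A variant is rare when its sample MAF is strictly below `threshold`
#' (default 0.05, the conventional rare-variant cutoff); the boundary value
#' itself is common.
#'
#' @param g a [ge_genotypes] object.
#' @param threshold rare/common MAF cutoff.
#' @returns an object of class `ge_partition`: list with integer index
#'   vectors `rare_idx` and `common_idx` (disjoint, covering all variants)
#'   and the `threshold`.
#' @examples
#' g <- ge_genotypes(cbind(v1 = c(0, 0, 1, 0), v2 = c(1, 2, 1, 1)))
#' classify_variants(g)
#' @export
classify_variants <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "ge_genotypes"), threshold > 0)
  rare <- which(g$maf < threshold)
  structure(
    list(rare_idx = rare,
         common_idx = setdiff(seq_along(g$maf), rare),
         threshold = threshold),
    class = "ge_partition"
  )
}

#' @export
print.ge_partition <- function(x, ...) {
  cat(sprintf("<ge_partition> %d rare / %d common (MAF < %g)\n",
              length(x$rare_idx), length(x$common_idx), x$threshold))
  invisible(x)
}

#' Build gene-environment interaction columns
#'
#' Elementwise products `E[i] * g[i, j]` between the environmental exposure
#' and each variant's minor-allele dosage -- the interaction terms whose
#' effects the region tests target.
#'
#' @param g a [ge_genotypes] object (or a bare dosage matrix).
#' @param E numeric environment vector, length `n`.
#' @returns an `n x m` numeric matrix, columns named by variant.
#' @export
build_interactions <- function(g, E) {
  dos <- if (inherits(g, "ge_genotypes")) g$dosages else g
  if (length(E) != nrow(dos)) {
    stop("length(E) [", length(E), "] does not match individuals [", nrow(dos), "].")
  }
  dos * as.numeric(E)
}
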