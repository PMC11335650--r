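#' @importFrom stats pnorm qnorm pchisq pt mad sd setNames rnorm runif complete.cases
#' @importFrom utils head
NULL

# z for a 95% normal interval; kept at full precision because printed
# CI-width inversions (or_to_beta) are sensitive to it
Z95 <- stats::qnorm(0.975)

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "NEA", "EAF", "BETA", "SE", "P", "N")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Canonical column names of a summary-statistics table
#'
#' @return Character vector: `SNP, CHR, POS, EA, NEA, EAF, BETA, SE, P, N`.
#' @export
sumstats_columns <- function() CANONICAL_COLS

#' Build a validated GWAS summary-statistics table
#'
#' Constructs the canonical per-SNP association table used throughout the
#' package: one row per biallelic SNP with effect allele (`EA`), other allele
#' (`NEA`), effect-allele frequency (`EAF`), per-allele effect (`BETA`, SD
#' units for continuous traits, log-odds for binary), standard error, p-value
#' and sample size. Alleles are upper-cased; rows violating the row
#' invariants (identical alleles, non-positive SE, frequency or p outside
#' their open intervals, non-positive position or N, indels/multi-allelic
#' codes) are dropped with a warning naming each offending row, and the
#' diagnostics are kept in the `"diagnostics"` attribute.
#'
#' @param df Data frame with the canonical columns (see [sumstats_columns()]).
#' @param trait_id Optional trait identifier stored as an attribute.
#' @param strict If `TRUE`, any invalid row is an error rather than a
#'   warning-plus-drop.
#' @return A `sumstats` tibble.
#' @export
as_sumstats <- function(df, trait_id = NULL, strict = FALSE) {
  missing <- setdiff(CANONICAL_COLS, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[CANONICAL_COLS]
  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  df$EA <- toupper(as.character(df$EA))
  df$NEA <- toupper(as.character(df$NEA))
  for (col in c("POS", "EAF", "BETA", "SE", "P", "N")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  problems <- validate_sumstats_rows(df)
  if (nrow(problems) > 0) {
    msg <- paste0("row ", problems$row, " (", problems$snp_id, "): ", problems$problem)
    if (strict) {
      stop("invalid summary-statistics rows:\n", paste(msg, collapse = "\n"), call. = FALSE)
    }
    warning("dropping ", nrow(problems), " invalid row(s):\n",
            paste(msg, collapse = "\n"), call. = FALSE)
    df <- df[-unique(problems$row), , drop = FALSE]
  }
  if (anyDuplicated(df$SNP)) {
    stop("duplicated snp_id within table: ",
         paste(unique(df$SNP[duplicated(df$SNP)]), collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("sumstats", class(df)),
            trait_id = trait_id %||% attr(df, "trait_id", exact = TRUE),
            diagnostics = problems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sumstats_rows <- function(df) {
  checks <- list(
    unparseable_numeric = !complete.cases(df[c("POS", "EAF", "BETA", "SE", "P", "N")]),
    invalid_allele      = !(df$EA %in% VALID_ALLELES) | !(df$NEA %in% VALID_ALLELES),
    identical_alleles   = df$EA == df$NEA,
    nonpositive_se      = !is.na(df$SE) & df$SE <= 0,
    eaf_out_of_range    = !is.na(df$EAF) & (df$EAF <= 0 | df$EAF >= 1),
    pvalue_out_of_range = !is.na(df$P) & (df$P <= 0 | df$P > 1),
    invalid_pos         = !is.na(df$POS) & df$POS < 1,
    invalid_n           = !is.na(df$N) & df$N < 2
  )
  out <- lapply(names(checks), function(nm) {
    idx <- which(checks[[nm]])
    if (length(idx) == 0) return(NULL)
    tibble::tibble(row = idx, snp_id = df$SNP[idx], problem = nm)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(row = integer(), snp_id = character(), problem = character()))
  }
  res[order(res$row), ]
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's headers, e.g. `c(SNP = "rsid", BETA = "effect")`. Unmapped
#'   canonical names must appear verbatim in the header.
#' @param trait_id Optional trait identifier.
#' @param strict Passed to [as_sumstats()].
#' @return A `sumstats` tibble in file order.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL, strict = FALSE) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad) > 0) {
      stop("column_map refers to absent column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(CANONICAL_COLS, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  as_sumstats(raw, trait_id = trait_id, strict = strict)
}

#' Write a summary-statistics table as TSV
#'
#' Numeric fields are written with a round-trip-exact representation, so
#' `read_sumstats(write_sumstats(t))` reproduces `t` field for field.
#'
#' @param table A `sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table)[CANONICAL_COLS], path, progress = FALSE)
  invisible(path)
}

#' Validate an LD r-squared matrix
#'
#' @param m Square numeric matrix with SNP ids as dimnames.
#' @param tol Symmetry/diagonal tolerance.
#' @return `m` with class `ld_matrix`.
#' @export
as_ld_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("LD matrix must carry SNP ids as dimnames", call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column ids disagree", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("LD matrix has non-finite entries", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop("LD matrix asymmetric beyond tolerance ", format(tol), call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > tol) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop("LD r-squared entries must lie in [0, 1]", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 1
  structure(m, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix from TSV
#'
#' Expects SNP ids in the header and in the first column.
#'
#' @param path Input path.
#' @param tol Validation tolerance, see [as_ld_matrix()].
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  as_ld_matrix(m, tol = tol)
}

#' Write an LD matrix as TSV
#'
#' @param m An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  df <- tibble::as_tibble(unclass(m))
  df <- tibble::add_column(df, SNP = rownames(m), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  tid <- attr(x, "trait_id", exact = TRUE)
  cat("GWAS summary statistics", if (!is.null(tid)) paste0("for ", tid), "-",
      nrow(x), "SNPs\n")
  NextMethod()
}
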