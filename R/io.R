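# Variant-table I/O. The exchange format is a UTF-8 TSV with a header row;
# HGVS strings are opaque identifiers (no transcript-aware normalization).

.known_columns <- c(
  "variant_id", "hgvs_c", "hgvs_p", "n_patients", "evidence",
  "sge_hap1", "sge_mes", "gvgd_grade", "variant_type",
  "lr_components", "combined_lr", "posterior"
)

# Unicode minus (U+2212), as printed in typeset tables, is accepted on input;
# ASCII is always emitted.
.ascii_minus <- function(x) gsub("−", "-", x)

.opt_chr <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))

#' Read a variant table
#'
#' Reads a tab-separated variant table with one row per variant. Required
#' columns: `evidence` (semicolon-separated ACMG/AMP tokens; may be blank)
#' and an identifier (`variant_id`, or `hgvs_c` used as the id). Recognized
#' optional columns: `hgvs_p`, `n_patients`, `sge_hap1`, `sge_mes` (level
#' names or signed points), `gvgd_grade`, `variant_type`, `lr_components`
#' (semicolon-separated non-negative reals), `combined_lr`, `posterior`.
#' Blank cells become missing fields. Any further columns are carried
#' through unparsed.
#'
#' @param path Path to the TSV file.
#' @param config Configuration list (reserved for category/prior overrides).
#' @return A data frame with one row per variant; `evidence` is a list
#'   column of parsed code data frames and `lr_components` a list column of
#'   numeric vectors.
#' @export
read_variant_table <- function(path, config = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8",
                           quote = "")
  raw[] <- lapply(raw, .ascii_minus)
  if (!"evidence" %in% names(raw)) {
    stop("variant table is missing required column 'evidence'", call. = FALSE)
  }
  if (!any(c("variant_id", "hgvs_c") %in% names(raw))) {
    stop("variant table needs a 'variant_id' or 'hgvs_c' column", call. = FALSE)
  }
  n <- nrow(raw)
  get <- function(col) if (col %in% names(raw)) .opt_chr(raw[[col]]) else rep(NA_character_, n)

  cell <- function(col, i, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("row %d, column '%s': %s", i, col, conditionMessage(e)),
           call. = FALSE)
    })
  }
  hgvs_c <- get("hgvs_c")
  variant_id <- get("variant_id")
  variant_id[is.na(variant_id)] <- hgvs_c[is.na(variant_id)]
  if (anyNA(variant_id)) {
    stop("row ", which(is.na(variant_id))[1], ": empty variant identifier",
         call. = FALSE)
  }
  bad_hgvs <- !is.na(hgvs_c) & !grepl("^c\\.[0-9*+-]", hgvs_c)
  if (any(bad_hgvs)) {
    stop("row ", which(bad_hgvs)[1], ", column 'hgvs_c': not a c. description: ",
         sQuote(hgvs_c[which(bad_hgvs)[1]]), call. = FALSE)
  }

  ev_raw <- get("evidence")
  evidence <- lapply(seq_len(n), function(i) {
    cell("evidence", i,
         if (is.na(ev_raw[i])) parse_evidence_code(character(0))
         else .as_codes(ev_raw[i]))
  })
  parse_num <- function(col) {
    x <- get(col)
    vapply(seq_len(n), function(i) {
      cell(col, i, {
        if (is.na(x[i])) return(NA_real_)
        v <- suppressWarnings(as.numeric(x[i]))
        if (is.na(v)) stop("not a number: ", sQuote(x[i]))
        v
      })
    }, numeric(1))
  }
  parse_sge <- function(col) {
    x <- get(col)
    vapply(seq_len(n), function(i) {
      cell(col, i, if (is.na(x[i])) NA_integer_ else sge_category(x[i]))
    }, integer(1))
  }
  n_patients <- parse_num("n_patients")
  if (any(!is.na(n_patients) & (n_patients < 0 | n_patients != round(n_patients)))) {
    stop("n_patients must be a non-negative integer", call. = FALSE)
  }
  lr_raw <- get("lr_components")
  lr_components <- lapply(seq_len(n), function(i) {
    cell("lr_components", i, {
      if (is.na(lr_raw[i])) return(NULL)
      v <- as.numeric(strsplit(lr_raw[i], ";", fixed = TRUE)[[1]])
      if (anyNA(v) || any(v < 0)) stop("invalid LR components: ", sQuote(lr_raw[i]))
      v
    })
  })
  combined_lr <- parse_num("combined_lr")
  both <- !is.na(combined_lr) & lengths(lr_components) > 0
  if (any(both)) {
    stop("row ", which(both)[1],
         ": supply either 'lr_components' or 'combined_lr', not both",
         call. = FALSE)
  }

  out <- data.frame(variant_id = variant_id, hgvs_c = hgvs_c,
                    hgvs_p = get("hgvs_p"), n_patients = n_patients,
                    sge_hap1 = parse_sge("sge_hap1"),
                    sge_mes = parse_sge("sge_mes"),
                    gvgd_grade = get("gvgd_grade"),
                    variant_type = get("variant_type"),
                    combined_lr = combined_lr,
                    posterior = parse_num("posterior"),
                    stringsAsFactors = FALSE)
  out$evidence <- evidence
  out$lr_components <- lr_components
  extra <- setdiff(names(raw), .known_columns)
  for (col in extra) out[[col]] <- .opt_chr(raw[[col]])
  out
}

#' Write a per-variant results table
#'
#' Writes a TSV with stable column order and fixed numeric formatting:
#' probabilities and likelihood ratios at three decimals, points as bare
#' integers, missing values as empty cells, ASCII minus signs throughout.
#' Identical input yields byte-identical output.
#'
#' @param results Per-variant data frame (e.g. `run_pipeline()$per_variant`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  fmt <- function(x, col) {
    if (is.list(x)) {
      x <- vapply(x, function(v) paste(format(v, trim = TRUE), collapse = ";"),
                  character(1))
    } else if (is.numeric(x) && col %in% c("combined_lr", "prior", "posterior")) {
      x <- ifelse(is.na(x), NA, sprintf("%.3f", x))
    } else if (is.numeric(x)) {
      x <- ifelse(is.na(x), NA, format(x, trim = TRUE, scientific = FALSE))
    }
    x <- as.character(x)
    x[is.na(x)] <- ""
    .ascii_minus(x)
  }
  out <- as.data.frame(mapply(fmt, results, names(results), SIMPLIFY = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
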