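# Seven-level SGE functional categories and PS3/BS3 integration of two
# SGE datasets (e.g. HAP1-cell and mES-cell assays).

# bijection between level names and signed points
.sge_points <- c(
  pathogenic_strong = 4L, pathogenic_moderate = 2L, pathogenic_supporting = 1L,
  uncertain = 0L,
  benign_supporting = -1L, benign_moderate = -2L, benign_strong = -4L
)

#' Parse an SGE functional-result category
#'
#' Each SGE dataset bins a variant into one of seven categories:
#' pathogenic strong / moderate / supporting, uncertain, and benign
#' supporting / moderate / strong, worth +4, +2, +1, 0, -1, -2, -4 evidence
#' points respectively. Input may be the level name (case-insensitive, e.g.
#' `"benign_strong"`) or the signed point value (`-4`, possibly with a
#' Unicode minus); the bijection makes these equivalent.
#'
#' @param x Character or numeric vector of categories.
#' @return Integer vector of signed category points (`NA` for missing input).
#' @export
sge_category <- function(x) {
  if (length(x) == 0L) return(integer(0))
  out <- rep(NA_integer_, length(x))
  if (is.numeric(x)) {
    val <- as.integer(x)
  } else {
    chr <- gsub("−", "-", trimws(as.character(x)))
    missing <- is.na(chr) | !nzchar(chr)
    byname <- .sge_points[tolower(chr)]
    val <- suppressWarnings(as.integer(chr))
    val[!is.na(byname)] <- byname[!is.na(byname)]
    val[missing] <- NA_integer_
    unresolved <- !missing & is.na(val)
    if (any(unresolved)) {
      stop("unrecognized SGE category: ",
           paste(sQuote(x[unresolved]), collapse = ", "), call. = FALSE)
    }
  }
  known <- is.na(val) | val %in% .sge_points
  if (!all(known)) {
    stop("SGE category points must be one of ",
         paste(sort(unique(.sge_points)), collapse = ", "), "; got ",
         paste(val[!known], collapse = ", "), call. = FALSE)
  }
  out[] <- val
  out
}

#' Level name for SGE category points
#'
#' @param points Integer vector of signed category points.
#' @return Character vector of level names (e.g. `"benign_strong"`).
#' @export
sge_level <- function(points) {
  points <- sge_category(points)
  names(.sge_points)[match(points, .sge_points)]
}

#' Binary functional call of an SGE category
#'
#' Positive category points are a pathogenic functional result, negative
#' points a benign one, zero an uncertain one.
#'
#' @param x SGE categories in any form accepted by [sge_category()].
#' @return Character vector with values `"pathogenic"`, `"benign"`,
#'   `"uncertain"` (and `NA` where the category is missing).
#' @export
functional_call <- function(x) {
  pts <- sge_category(x)
  ifelse(is.na(pts), NA_character_,
    ifelse(pts > 0, "pathogenic", ifelse(pts < 0, "benign", "uncertain")))
}

#' Integrate two SGE functional results into PS3/BS3 evidence
#'
#' When the two datasets agree in direction (both pathogenic or both benign)
#' a PS3-family or BS3-family code is assigned at the stronger of the two
#' category levels: |points| 4 maps to strong (`PS3`/`BS3`), 2 to moderate
#' (`PS3_M`/`BS3_M`), and 1 to supporting (`PS3_P`/`BS3_P`), the
#' supporting-level downgrade for weakly concordant pairs. If exactly one
#' call is uncertain, or the signs are opposite, the pair is discordant and
#' no functional evidence is assigned. Two uncertain calls are uninformative
#' (no evidence, but not counted as discordant).
#'
#' @param hap1,mes The two datasets' categories, any form accepted by
#'   [sge_category()].
#' @return A list with `status` (one of `"concordant_pathogenic"`,
#'   `"concordant_benign"`, `"discordant"`, `"uninformative"`), `code` (the
#'   assigned token, or `NA`), and `evidence` (the parsed code, or `NULL`).
#' @examples
#' integrate_sge(4, 4)    # PS3 at strong
#' integrate_sge(-1, -1)  # BS3_P: supporting-level downgrade
#' integrate_sge(4, 0)    # discordant, no evidence
#' @export
integrate_sge <- function(hap1, mes) {
  h <- sge_category(hap1)
  m <- sge_category(mes)
  stopifnot(length(h) == 1L, length(m) == 1L, !is.na(h), !is.na(m))
  ch <- functional_call(h)
  cm <- functional_call(m)
  status <- if (ch == "uncertain" && cm == "uncertain") {
    "uninformative"
  } else if (ch == cm) {
    paste0("concordant_", ch)
  } else {
    "discordant"
  }
  code <- NA_character_
  if (startsWith(status, "concordant")) {
    fam <- if (ch == "pathogenic") "PS3" else "BS3"
    suffix <- switch(as.character(max(abs(h), abs(m))),
                     "4" = "", "2" = "_M", "1" = "_P")
    code <- paste0(fam, suffix)
  }
  list(status = status, code = code,
       evidence = if (is.na(code)) NULL else parse_evidence_code(code))
}

#' Reclassify a variant after SGE evidence integration
#'
#' Classifies the variant from its existing evidence codes, integrates the
#' two SGE results, and -- when integration yields a PS3/BS3-family code --
#' appends it and reclassifies. The evidence list must not already contain a
#' functional (PS3/BS3-family) code.
#'
#' @param codes Existing evidence codes, any form accepted by
#'   [aggregate_points()].
#' @inheritParams integrate_sge
#' @return A list with `pre` and `post` ([classify_variant()] results before
#'   and after integration), `integration` (the [integrate_sge()] result) and
#'   `reclassified` (logical: did the label change).
#' @export
apply_integration <- function(codes, hap1, mes) {
  codes <- .as_codes(codes)
  if (any(codes$base %in% c("PS3", "BS3"))) {
    stop("evidence already contains a functional PS3/BS3-family code; ",
         "remove it before integrating SGE results", call. = FALSE)
  }
  pre <- classify_variant(codes)
  integ <- integrate_sge(hap1, mes)
  post <- if (is.null(integ$evidence)) pre else
    classify_variant(rbind(codes, integ$evidence))
  list(pre = pre, integration = integ, post = post,
       reclassified = !identical(pre$label, post$label))
}
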