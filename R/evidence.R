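# ACMG/AMP evidence-code parsing and point-based classification.

#' Five-tier classification labels, benign to pathogenic
#'
#' @return Character vector `c("BV", "LBV", "VUS", "LPV", "PV")` in order of
#'   increasing pathogenicity (benign, likely benign, uncertain significance,
#'   likely pathogenic, pathogenic).
#' @export
class_levels <- function() c("BV", "LBV", "VUS", "LPV", "PV")

# point magnitude is a function of strength alone
.strength_points <- c(
  supporting = 1L, moderate = 2L, strong = 4L, very_strong = 8L
)

.suffix_strength <- c(P = "supporting", M = "moderate", S = "strong", VS = "very_strong")

# default strength per code family when no suffix modifies it
.family_default <- c(
  PVS = "very_strong", PS = "strong", PM = "moderate", PP = "supporting",
  BA = "stand_alone", BS = "strong", BP = "supporting"
)

#' Parse ACMG/AMP evidence-code tokens
#'
#' Tokens follow the grammar `FAMILY` + number + optional strength suffix,
#' e.g. `PVS1`, `PM2_P`, `BS1`, `BP7_S`. Suffixes `_P`, `_M`, `_S`, `_VS`
#' override the family-default strength (supporting, moderate, strong, very
#' strong). A trailing parenthetical comment such as `"BP7_S (RNA)"` is
#' accepted and ignored. Pathogenic families (`PVS`, `PS`, `PM`, `PP`) carry
#' positive points, benign families (`BS`, `BP`) negative; magnitude is 1, 2,
#' 4 or 8 by strength. `BA` (stand-alone benign) carries no points and is
#' handled by [classify_variant()].
#'
#' @param tokens Character vector of evidence-code tokens.
#' @return A data frame with one row per token and columns `label` (canonical
#'   token), `base` (family + number, e.g. `"PM2"`), `family`, `direction`
#'   (`"pathogenic"` or `"benign"`), `strength`, and integer `points`.
#' @examples
#' parse_evidence_code(c("PVS1", "PM2_P", "BP7_S (RNA)"))
#' @export
parse_evidence_code <- function(tokens) {
  tokens <- as.character(tokens)
  stripped <- sub("\\s*\\([^)]*\\)\\s*$", "", trimws(tokens))
  m <- regmatches(stripped,
                  regexec("^(PVS|PS|PM|PP|BA|BS|BP)([0-9]+)(?:_(P|M|S|VS))?$",
                          stripped, perl = TRUE))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    stop("malformed evidence-code token: ", paste(sQuote(tokens[bad]), collapse = ", "),
         call. = FALSE)
  }
  family <- vapply(m, `[`, character(1), 2L)
  number <- vapply(m, `[`, character(1), 3L)
  suffix <- vapply(m, `[`, character(1), 4L)
  strength <- ifelse(suffix == "", .family_default[family],
                     .suffix_strength[suffix])
  if (any(family == "BA" & suffix != "")) {
    stop("stand-alone code cannot take a strength suffix: ",
         paste(sQuote(tokens[family == "BA" & suffix != ""]), collapse = ", "),
         call. = FALSE)
  }
  direction <- ifelse(substr(family, 1, 1) == "P", "pathogenic", "benign")
  pts <- ifelse(strength == "stand_alone", 0L,
                unname(.strength_points[strength]))
  pts <- as.integer(pts) * ifelse(direction == "pathogenic", 1L, -1L)
  data.frame(
    label = ifelse(suffix == "", paste0(family, number),
                   paste0(family, number, "_", suffix)),
    base = paste0(family, number),
    family = family,
    direction = direction,
    strength = unname(strength),
    points = pts,
    stringsAsFactors = FALSE
  )
}

#' Render parsed evidence codes back to tokens
#'
#' Inverse of [parse_evidence_code()]: family-default strengths render without
#' a suffix, modified strengths with `_P`/`_M`/`_S`/`_VS`.
#'
#' @param codes Data frame as returned by [parse_evidence_code()].
#' @return Character vector of tokens.
#' @export
format_evidence_code <- function(codes) {
  codes <- .as_codes(codes)
  codes$label
}

# accept either tokens (character, possibly semicolon-separated) or a parsed
# data frame everywhere codes are taken
.as_codes <- function(codes) {
  if (is.data.frame(codes)) {
    stopifnot(all(c("base", "points") %in% names(codes)))
    return(codes)
  }
  if (is.null(codes) || length(codes) == 0L) {
    return(parse_evidence_code(character(0)))
  }
  tokens <- unlist(strsplit(as.character(codes), ";", fixed = TRUE))
  tokens <- trimws(tokens)
  parse_evidence_code(tokens[nzchar(tokens)])
}

#' Sum signed evidence points
#'
#' @param codes Parsed evidence codes (data frame) or a character vector of
#'   tokens (optionally one semicolon-separated string).
#' @return Integer sum of signed points; `0` for empty input. Stand-alone
#'   codes contribute no points.
#' @details At most one code per base family may be applied; duplicates (e.g.
#'   `PS3` together with `PS3_P`) are an error -- a family is never
#'   double-counted.
#' @examples
#' aggregate_points(c("PVS1", "PM2_P", "PM5_S")) # 13
#' aggregate_points("BS1;BP4;BP7")               # -6
#' @export
aggregate_points <- function(codes) {
  codes <- .as_codes(codes)
  dup <- duplicated(codes$base)
  if (any(dup)) {
    stop("duplicate evidence family applied: ",
         paste(sQuote(unique(codes$base[dup])), collapse = ", "), call. = FALSE)
  }
  if (nrow(codes) == 0L) return(0L)
  as.integer(sum(codes$points))
}

#' Map aggregated points to the five-tier class
#'
#' Thresholds: pathogenic (PV) at >= 10 points, likely pathogenic (LPV) 6 to
#' 9, uncertain (VUS) -1 to 5, likely benign (LBV) -6 to -2, benign (BV) at
#' <= -7. The integer bands are exhaustive and disjoint.
#'
#' @param total_points Integer vector of aggregated points.
#' @return Character vector of labels from [class_levels()].
#' @export
classify_points <- function(total_points) {
  stopifnot(is.numeric(total_points), all(total_points == round(total_points)))
  ifelse(total_points >= 10, "PV",
    ifelse(total_points >= 6, "LPV",
      ifelse(total_points >= -1, "VUS",
        ifelse(total_points >= -6, "LBV", "BV"))))
}

#' Classify a variant from its applied evidence codes
#'
#' Aggregates signed points and maps the total to the five-tier class. A
#' stand-alone benign code (`BA1`) short-circuits the classification to `BV`
#' regardless of the point total; it contributes no points and the result
#' flags that the short-circuit fired.
#'
#' @inheritParams aggregate_points
#' @return A list of class `"classification"` with elements `total_points`,
#'   `label`, `applied_codes` (parsed data frame) and `stand_alone` (logical).
#' @examples
#' classify_variant("PVS1;PM2_P;PM5_S") # 13 points, PV
#' @export
classify_variant <- function(codes) {
  codes <- .as_codes(codes)
  total <- aggregate_points(codes)
  stand_alone <- any(codes$strength == "stand_alone")
  label <- if (stand_alone) "BV" else classify_points(total)
  structure(
    list(total_points = total, label = label,
         applied_codes = codes, stand_alone = stand_alone),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  codes <- paste(x$applied_codes$label, collapse = ", ")
  cat(sprintf("<classification> %s (%+d points)%s\n  codes: %s\n",
              x$label, x$total_points,
              if (x$stand_alone) " [stand-alone benign]" else "",
              if (nzchar(codes)) codes else "<none>"))
  invisible(x)
}
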