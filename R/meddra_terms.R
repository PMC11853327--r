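#' Built-in MedDRA preferred-term dictionary
#'
#' Returns the fixed dictionary mapping MedDRA preferred terms (PTs) to the
#' two medical conditions screened by the pipeline: treatment *resistance*
#' (2 PTs) and treatment *ineffectiveness* (11 PTs). The dictionary ships as a
#' plain CSV under `inst/extdata/` so other condition sets can be supplied via
#' the `path` argument of the reader functions.
#'
#' @param path Optional path to an alternative dictionary CSV with columns
#'   `code,pt_name,condition`. Defaults to the packaged dictionary.
#' @return A tibble with columns `code` (integer MedDRA code), `pt_name`
#'   (canonical PT string) and `condition` (factor with levels
#'   `resistance`, `ineffectiveness`).
#' @export
#' @examples
#' meddra_dictionary()
meddra_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "meddra_conditions.csv",
                        package = "rorsignal", mustWork = TRUE)
  }
  dict <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_integer(),
      pt_name = readr::col_character(),
      condition = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- setdiff(unique(dict$condition), c("resistance", "ineffectiveness"))
  if (length(bad) > 0) {
    stop("dictionary contains unknown condition labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(dict$code) > 0) {
    stop("dictionary codes must be unique", call. = FALSE)
  }
  dict$condition <- factor(dict$condition,
                           levels = c("resistance", "ineffectiveness"))
  tibble::as_tibble(dict)
}

#' Condition labels recognised by the pipeline
#'
#' @return Character vector of the three labels: the two dictionary conditions
#'   plus `"other"` for any PT absent from the dictionary.
#' @export
condition_levels <- function() c("resistance", "ineffectiveness", "other")

#' Classify preferred terms into medical conditions
#'
#' Maps MedDRA PTs to `resistance`, `ineffectiveness` or `other`. Matching is
#' by numeric code when a code is given, otherwise by case-insensitive exact
#' name match after whitespace trimming. No fuzzy matching is attempted: a PT
#' absent from the dictionary is always `other`, never silently attached to a
#' condition. When both code and name are supplied and disagree, the code wins
#' and a warning is raised.
#'
#' @param code Integer MedDRA code(s), or `NA` where only a name is available.
#' @param name PT name string(s), or `NA` where only a code is available.
#'   Either argument may be omitted, but each element must carry at least one
#'   identifier.
#' @param dictionary Dictionary tibble, as from [meddra_dictionary()].
#' @return Factor of condition labels (levels [condition_levels()]), one per
#'   input element.
#' @export
#' @examples
#' classify_pt(code = 10059866)
#' classify_pt(name = "drug ineffective")
#' classify_pt(name = "Nausea")
classify_pt <- function(code = NULL, name = NULL,
                        dictionary = meddra_dictionary()) {
  if (is.null(code) && is.null(name)) {
    stop("supply at least one of `code` or `name`", call. = FALSE)
  }
  n <- max(length(code), length(name))
  if (n == 0L) stop("empty PT identifier", call. = FALSE)
  if (is.null(code)) code <- rep(NA_integer_, n)
  if (is.null(name)) name <- rep(NA_character_, n)
  code <- rep_len(suppressWarnings(as.integer(code)), n)
  name <- rep_len(as.character(name), n)
  name_norm <- tolower(trimws(name))
  name_norm[!is.na(name_norm) & name_norm == ""] <- NA_character_
  if (any(is.na(code) & is.na(name_norm))) {
    stop("each PT must have a non-empty code or name", call. = FALSE)
  }

  dict_cond <- as.character(dictionary$condition)
  by_code <- dict_cond[match(code, dictionary$code)]
  by_name <- dict_cond[match(name_norm, tolower(dictionary$pt_name))]

  out <- ifelse(!is.na(code),
                ifelse(is.na(by_code), "other", by_code),
                ifelse(is.na(by_name), "other", by_name))

  conflict <- !is.na(code) & !is.na(name_norm) &
    !is.na(by_code) & !is.na(by_name) & by_code != by_name
  if (any(conflict)) {
    warning(sum(conflict),
            " PT(s) where code and name map to different conditions;",
            " the code was used", call. = FALSE)
  }
  factor(out, levels = condition_levels())
}
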