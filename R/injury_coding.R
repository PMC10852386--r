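#' ICD-10 external-cause injury categorization
#'
#' Maps ICD-10 external-cause codes to injury-mechanism categories via a
#' prefix-pattern matrix (a bundled subset of the standard external-cause
#' framework ships in `inst/extdata/injury_matrix.csv`; a user-supplied full
#' matrix in the same format is accepted), and resolves each admission to
#' exactly one analysis category with most-specific-code tie-breaking.
#'
#' @name injury_coding
#' @keywords internal
NULL

#' The fifteen base injury categories
#' @export
BASE_CATEGORIES <- c("cut_pierce", "drowning", "fall", "fire_burn",
                     "environmental", "motor_vehicle_traffic",
                     "transportation_other", "poisoning_drug",
                     "poisoning_nondrug", "overexertion", "machinery",
                     "firearm", "struck_by_against", "suffocation", "other")

#' The fourteen resolved analysis categories
#' @export
RESOLVED_CATEGORIES <- c("cut_pierce", "drowning", "fall", "fire_burn",
                         "environmental", "transport", "poisoning",
                         "overexertion", "machinery", "firearm",
                         "struck_by_against", "suffocation",
                         "other_specified", "multiple")

#' Load an injury matrix of code-prefix patterns
#'
#' @param path CSV with columns `pattern` (an ICD-10 code prefix, dots
#'   ignored) and `category` (one of [BASE_CATEGORIES]). Longer prefixes take
#'   precedence when several match a code.
#' @return data.frame of class `injury_matrix`.
#' @export
load_injury_matrix <- function(path = system.file("extdata",
                                                  "injury_matrix.csv",
                                                  package = "outagecc")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(m) == 0L) stop("empty injury matrix")
  if (!all(c("pattern", "category") %in% names(m)))
    stop("injury matrix needs columns pattern, category")
  m$pattern <- toupper(gsub("[. ]", "", m$pattern))
  bad <- setdiff(unique(m$category), BASE_CATEGORIES)
  if (length(bad) > 0L)
    stop("unknown injury categories: ", paste(bad, collapse = ", "))
  dup <- unique(m$pattern[duplicated(m$pattern)])
  conflict <- dup[vapply(dup, function(p)
    length(unique(m$category[m$pattern == p])) > 1L, logical(1))]
  if (length(conflict) > 0L)
    stop("conflicting duplicate patterns: ", paste(conflict, collapse = ", "))
  m <- m[!duplicated(m$pattern), , drop = FALSE]
  ## longest patterns first: longest-prefix precedence by construction
  m <- m[order(-nchar(m$pattern), m$pattern), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("injury_matrix", "data.frame")
  m
}

#' Base categories matched by a record's diagnosis codes
#'
#' All diagnosis fields contribute; each code is matched against the matrix
#' by longest prefix; unmatched codes are ignored (a record whose codes all
#' fail to match resolves to "unspecified" and is excluded downstream).
#'
#' @param codes character vector of ICD-10 codes (any diagnosis position).
#' @param matrix an [load_injury_matrix()] result.
#' @return character vector: the set (no duplicates) of matched base
#'   categories, possibly empty.
#' @export
extract_categories <- function(codes, matrix) {
  codes <- toupper(gsub("[. ]", "", codes))
  codes <- codes[!is.na(codes) & nzchar(codes)]
  cats <- vapply(codes, function(code) {
    hit <- which(startsWith(code, matrix$pattern))
    if (length(hit) == 0L) NA_character_ else matrix$category[hit[1L]]
  }, character(1))
  unique(cats[!is.na(cats)])
}

#' Resolve a set of base categories to one analysis category
#'
#' Rules, in order: (1) merge motor-vehicle (traffic) with transportation
#' (other) into `transport`, and drug with non-drug poisoning into
#' `poisoning`; (2) records carrying both poisoning and fire/burn are
#' attributed to fire/burn (smoke-inhalation admissions dominate that
#' combination); (3) the unspecific `other` category is dropped whenever a
#' specific category is present (most-specific-code rule); (4) a single
#' remaining category wins; (5) two or more remaining specific categories
#' resolve to `multiple`; (6) `other` alone resolves to `other_specified`;
#' (7) an empty set is `unspecified` (excluded from analysis).
#'
#' @param categories character vector of base categories (set semantics:
#'   duplicates and order are irrelevant).
#' @return a single category label from [RESOLVED_CATEGORIES] or
#'   `"unspecified"`.
#' @export
resolve_category <- function(categories) {
  s <- unique(categories)
  bad <- setdiff(s, BASE_CATEGORIES)
  if (length(bad) > 0L) stop("unknown base categories: ",
                             paste(bad, collapse = ", "))
  s[s %in% c("motor_vehicle_traffic", "transportation_other")] <- "transport"
  s[s %in% c("poisoning_drug", "poisoning_nondrug")] <- "poisoning"
  s <- unique(s)
  if (all(c("poisoning", "fire_burn") %in% s)) s <- setdiff(s, "poisoning")
  specific <- setdiff(s, "other")
  if (length(specific) == 0L) {
    if ("other" %in% s) return("other_specified")
    return("unspecified")
  }
  if (length(specific) == 1L) return(specific)
  "multiple"
}

#' Resolve every record in a table
#'
#' @param records data.frame whose diagnosis codes are in columns named
#'   `dx1`, `dx2`, ... (empty string or `NA` = no code).
#' @param matrix injury matrix.
#' @return `records` with a `category` column appended.
#' @export
resolve_records <- function(records, matrix) {
  dxcols <- grep("^dx", names(records), value = TRUE)
  if (length(dxcols) == 0L) stop("records carry no dx* diagnosis columns")
  n <- nrow(records)
  codes <- toupper(gsub("[. ]", "", as.matrix(records[dxcols])))
  ## categorize each distinct code once, then resolve per record
  ucodes <- unique(as.vector(codes))
  ucodes <- ucodes[!is.na(ucodes) & nzchar(ucodes)]
  ucat <- vapply(ucodes, function(code) {
    hit <- which(startsWith(code, matrix$pattern))
    if (length(hit) == 0L) NA_character_ else matrix$category[hit[1L]]
  }, character(1))
  catm <- ucat[match(codes, ucodes)]
  dim(catm) <- c(n, length(dxcols))
  records$category <- vapply(seq_len(n), function(i) {
    ci <- catm[i, ]
    resolve_category(ci[!is.na(ci)])
  }, character(1))
  records
}

#' Two-stage analyzability filter
#'
#' Stage 1 drops records without a specified injury category; stage 2 drops
#' records lacking a block-group-to-POL linkage to a QC-retained POL (no
#' usable exposure). Both stages are tallied separately, with percentages of
#' the input count.
#'
#' @param records data.frame with `category` and `bg_id`.
#' @param mapping block-group mapping from [assign_blockgroup_to_pol()].
#' @param retained_pols character vector of QC-retained POL ids; defaults to
#'   every POL appearing in `mapping`.
#' @return list: `retained` records, `tally` (counts and percentages at each
#'   stage).
#' @export
filter_analyzable <- function(records, mapping,
                              retained_pols = unique(stats::na.omit(mapping$pol_id))) {
  n0 <- nrow(records)
  specified <- records$category != "unspecified"
  r1 <- records[specified, , drop = FALSE]
  pol <- mapping$pol_id[match(r1$bg_id, mapping$bg_id)]
  linked <- !is.na(pol) & pol %in% retained_pols
  r2 <- r1[linked, , drop = FALSE]
  tally <- list(n_input = n0,
                n_specified = nrow(r1),
                pct_specified = 100 * nrow(r1) / n0,
                n_complete = nrow(r2),
                pct_complete = 100 * nrow(r2) / n0,
                n_dropped_unspecified = n0 - nrow(r1),
                n_dropped_unlinked = nrow(r1) - nrow(r2))
  list(retained = r2, tally = tally)
}

#' Demographic and cause-of-injury summary of analyzable records
#'
#' Counts and within-age-band percentages by cause of injury for the four
#' pediatric age bands (<1, 1-5, 6-10, 11-17), and the urbanicity
#' distribution of admissions.
#'
#' @param records data.frame with `age`, `category` and optionally
#'   `urbanicity`.
#' @return list: `by_age_category` (category x age-band counts and column
#'   percentages), `by_urbanicity` (counts and percentages, when available).
#' @export
summarize_admissions <- function(records) {
  band <- cut(records$age, c(-Inf, 0, 5, 10, 17), right = TRUE,
              labels = c("<1", "1-5", "6-10", "11-17"))
  tab <- table(records$category, band)
  pct <- 100 * sweep(tab, 2L, pmax(colSums(tab), 1L), "/")
  out <- list(by_age_category = list(counts = tab, pct = pct))
  if ("urbanicity" %in% names(records)) {
    ut <- table(records$urbanicity)
    out$by_urbanicity <- data.frame(class = names(ut), n = as.integer(ut),
                                    pct = 100 * as.integer(ut) / nrow(records))
  }
  out
}
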