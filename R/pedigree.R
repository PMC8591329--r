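#' @importFrom stats sd var setNames aggregate complete.cases
#' @importFrom utils read.table write.table packageVersion
NULL

#' Tactic levels used throughout the package
#'
#' The three reproductive tactics: females, large fighting males
#' ("hooknose"), and small sneaking males ("jack").  Females are treated as
#' a tactic so that selection and inheritance can be compared on the same
#' footing across all three classes.
#'
#' @export
TACTICS <- c("female", "hooknose", "jack")

.SEXES <- c("female", "male")
.GENERATIONS <- c("parent", "offspring")

#' Column-name mapping for pedigree files
#'
#' Maps the package's canonical column names onto the headers actually
#' present in a delimited pedigree file.
#'
#' @param id,sex,tactic,year,length_mm,rs,dam_id,sire_id,generation header
#'   names in the input file for each canonical field.  `tactic` and
#'   `generation` may be absent from the file (see [read_pedigree()]).
#' @return A named character vector of class `pedigree_dialect`.
#' @export
pedigree_dialect <- function(id = "id", sex = "sex", tactic = "tactic",
                             year = "year", length_mm = "length_mm",
                             rs = "rs", dam_id = "dam_id",
                             sire_id = "sire_id",
                             generation = "generation") {
  d <- c(id = id, sex = sex, tactic = tactic, year = year,
         length_mm = length_mm, rs = rs, dam_id = dam_id,
         sire_id = sire_id, generation = generation)
  class(d) <- "pedigree_dialect"
  d
}

#' Male tactic classification rule
#'
#' Males below the length threshold are classified as jacks (early-maturing
#' sneakers), males at or above it as hooknose males.  The default 500 mm
#' threshold reflects the bimodal male length distribution in wild coho.
#'
#' @param threshold_mm positive length threshold in mm.
#' @return A list of class `tactic_rule`.
#' @export
tactic_rule <- function(threshold_mm = 500) {
  if (!is.numeric(threshold_mm) || length(threshold_mm) != 1 ||
      !is.finite(threshold_mm) || threshold_mm <= 0)
    stop("`threshold_mm` must be a single positive number", call. = FALSE)
  structure(list(threshold_mm = threshold_mm), class = "tactic_rule")
}

#' Classify a male's tactic from length at maturity
#'
#' @param length_mm vector of positive fork lengths (mm).
#' @param rule a [tactic_rule()]; classification is jack strictly below the
#'   threshold, hooknose at or above it.
#' @return Character vector, `"jack"` or `"hooknose"`.
#' @examples
#' classify_male_tactic(c(423, 530, 500))
#' @export
classify_male_tactic <- function(length_mm, rule = tactic_rule()) {
  stopifnot(inherits(rule, "tactic_rule"))
  if (!is.numeric(length_mm) || any(!is.finite(length_mm)) ||
      any(length_mm <= 0))
    stop("lengths must be positive and finite", call. = FALSE)
  ifelse(length_mm < rule$threshold_mm, "jack", "hooknose")
}

.norm_missing <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | toupper(x) %in% c("NA", "NONE", "0"))] <- NA
  x
}

#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sex`, `tactic`, `year`, `length_mm`, `rs`, `dam_id`, `sire_id`,
#' `generation`.  Missing parents are `NA`.  `length_mm`/`rs` may be `NA`
#' (removed later by [filter_pedigree()]); non-missing values must satisfy
#' the individual-level invariants.
#'
#' Validation enforces: unique ids; sex in female/male; tactic = female
#' exactly for females; positive lengths; nonnegative integer reproductive
#' success; parent references resolve to individuals of the correct sex;
#' no individual is its own ancestor; and, when both generations carry
#' years, every parent-generation year precedes every offspring-generation
#' year.  Violations raise an error naming the offending rows/ids.
#'
#' If `generation` is absent it is inferred: rows with at least one
#' non-missing parent link are `"offspring"`, the rest `"parent"`.  If
#' `tactic` is absent it is derived from sex and [classify_male_tactic()].
#'
#' @param df data frame of individuals.
#' @param rule [tactic_rule()] used only when the tactic column is absent;
#'   tactics present in the input are retained as-is.
#' @return The validated data frame with class `c("pedigree","data.frame")`.
#' @export
as_pedigree <- function(df, rule = tactic_rule()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("id", "sex", "year", "length_mm", "rs")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  df$id <- as.character(df$id)
  df$sex <- as.character(df$sex)
  df$year <- as.integer(df$year)
  df$length_mm <- as.numeric(df$length_mm)
  rs_raw <- suppressWarnings(as.numeric(df$rs))
  if (!"dam_id" %in% names(df)) df$dam_id <- NA_character_
  if (!"sire_id" %in% names(df)) df$sire_id <- NA_character_
  df$dam_id <- .norm_missing(df$dam_id)
  df$sire_id <- .norm_missing(df$sire_id)

  problems <- character(0)
  bad_row <- function(which, msg) {
    if (any(which, na.rm = TRUE))
      problems <<- c(problems, paste0(
        msg, ": ", paste(df$id[which %in% TRUE], collapse = ", ")))
  }

  if (anyDuplicated(df$id))
    problems <- c(problems, paste0("duplicated id(s): ",
      paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  bad_row(!df$sex %in% .SEXES, "sex must be 'female' or 'male'")
  bad_row(!is.na(df$length_mm) & df$length_mm <= 0,
          "length_mm must be positive")
  bad_row(!is.na(rs_raw) & (rs_raw < 0 | rs_raw != round(rs_raw)),
          "rs must be a nonnegative integer")
  df$rs <- as.integer(round(rs_raw))

  if (!"tactic" %in% names(df) || all(is.na(df$tactic))) {
    df$tactic <- ifelse(df$sex == "female", "female",
                        ifelse(is.na(df$length_mm), NA_character_,
                               classify_male_tactic(
                                 pmax(df$length_mm, 1e-9), rule)))
  } else {
    df$tactic <- as.character(df$tactic)
  }
  bad_row(!is.na(df$tactic) & !df$tactic %in% TACTICS,
          "tactic must be female/hooknose/jack")
  bad_row(df$sex == "female" & !is.na(df$tactic) & df$tactic != "female",
          "females must have tactic 'female'")
  bad_row(df$sex == "male" & !is.na(df$tactic) & df$tactic == "female",
          "males cannot have tactic 'female'")

  if (!"generation" %in% names(df) || all(is.na(df$generation))) {
    df$generation <- ifelse(!is.na(df$dam_id) | !is.na(df$sire_id),
                            "offspring", "parent")
  } else {
    df$generation <- as.character(df$generation)
    bad_row(!df$generation %in% .GENERATIONS,
            "generation must be 'parent' or 'offspring'")
  }

  # parent references: must exist and have the right sex
  sex_of <- setNames(df$sex, df$id)
  dangling_dam <- !is.na(df$dam_id) & !df$dam_id %in% df$id
  dangling_sire <- !is.na(df$sire_id) & !df$sire_id %in% df$id
  bad_row(dangling_dam, "dam_id not found in pedigree")
  bad_row(dangling_sire, "sire_id not found in pedigree")
  bad_dam <- !is.na(df$dam_id) & !dangling_dam &
    sex_of[df$dam_id] != "female"
  bad_sire <- !is.na(df$sire_id) & !dangling_sire &
    sex_of[df$sire_id] != "male"
  if (any(bad_dam))
    problems <- c(problems, paste0("dam_id refers to a non-female: ",
      paste(unique(df$dam_id[bad_dam]), collapse = ", ")))
  if (any(bad_sire))
    problems <- c(problems, paste0("sire_id refers to a non-male: ",
      paste(unique(df$sire_id[bad_sire]), collapse = ", ")))
  bad_row(!is.na(df$dam_id) & df$dam_id == df$id |
          !is.na(df$sire_id) & df$sire_id == df$id,
          "individual is its own parent")

  py <- df$year[df$generation == "parent"]
  oy <- df$year[df$generation == "offspring"]
  if (length(py) && length(oy) &&
      !all(is.na(py)) && !all(is.na(oy)) &&
      max(py, na.rm = TRUE) >= min(oy, na.rm = TRUE))
    problems <- c(problems, sprintf(
      "parent-generation years must precede offspring-generation years (max parent year %d >= min offspring year %d)",
      max(py, na.rm = TRUE), min(oy, na.rm = TRUE)))

  if (length(problems))
    stop("pedigree validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  df <- df[, c("id", "sex", "tactic", "year", "length_mm", "rs",
               "dam_id", "sire_id", "generation")]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a pedigree from a delimited text file
#'
#' @param path path to a CSV/TSV file with one row per individual.
#' @param dialect a [pedigree_dialect()] mapping canonical names to the
#'   file's headers.
#' @param delim field delimiter; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param rule [tactic_rule()] applied only if the tactic column is absent.
#' @return A validated pedigree (see [as_pedigree()]).
#' @export
read_pedigree <- function(path, dialect = pedigree_dialect(),
                          delim = NULL, rule = tactic_rule()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  need <- dialect[c("id", "sex", "year", "length_mm", "rs")]
  miss <- setdiff(unname(need), names(raw))
  if (length(miss))
    stop("input file lacks mapped column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(id = raw[[dialect[["id"]]]],
                    sex = raw[[dialect[["sex"]]]],
                    year = raw[[dialect[["year"]]]],
                    length_mm = raw[[dialect[["length_mm"]]]],
                    rs = raw[[dialect[["rs"]]]],
                    stringsAsFactors = FALSE)
  for (f in c("tactic", "dam_id", "sire_id", "generation"))
    if (dialect[[f]] %in% names(raw)) out[[f]] <- raw[[dialect[[f]]]]
  as_pedigree(out, rule = rule)
}

#' Write a pedigree to a delimited text file
#'
#' @param p a pedigree.
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(p, path, delim = ",") {
  stopifnot(inherits(p, "pedigree"))
  utils::write.table(as.data.frame(p), path, sep = delim,
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Subset a pedigree by year, tactic, and generation
#'
#' Filter semantics: `NULL` means "no filter on this field"; a zero-length
#' vector is a vacuous filter and returns an empty pedigree.  Composing two
#' subsets equals a single subset with intersected filters.
#'
#' @param p a pedigree.
#' @param years optional integer vector of return years.
#' @param tactics optional character vector of tactics.
#' @param generation optional, `"parent"` or `"offspring"`.
#' @return A pedigree containing the matching individuals.
#' @export
subset_pedigree <- function(p, years = NULL, tactics = NULL,
                            generation = NULL) {
  stopifnot(inherits(p, "pedigree"))
  keep <- rep(TRUE, nrow(p))
  if (!is.null(years)) keep <- keep & p$year %in% as.integer(years)
  if (!is.null(tactics)) keep <- keep & p$tactic %in% tactics
  if (!is.null(generation)) keep <- keep & p$generation %in% generation
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Explicit cohort filtering with a log
#'
#' Drops individuals failing the study-inclusion filters, mirroring the
#' usual wild-pedigree conventions: length and reproductive success must be
#' present; optionally offspring must have both parents known; optionally
#' an origin column (if the caller supplies one) must equal `"wild"` for
#' the individual and both of its parents.  Each pass is logged with the
#' number of rows removed; the log is attached as attribute
#' `"filter_log"` and printed via `message()` when `verbose = TRUE`.
#'
#' @param p a pedigree.
#' @param require_length,require_rs drop rows with missing length / rs.
#' @param require_both_parents drop offspring lacking a dam or a sire.
#' @param origin optional character vector (parallel to rows of `p`) of
#'   origins; when given, non-`"wild"` individuals and offspring of
#'   non-wild parents are dropped.
#' @param verbose emit one `message()` per pass.
#' @return Filtered pedigree with a `filter_log` attribute
#'   (data frame: pass, removed, remaining).
#' @export
filter_pedigree <- function(p, require_length = TRUE, require_rs = TRUE,
                            require_both_parents = FALSE, origin = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(p, "pedigree"))
  log <- data.frame(pass = character(0), removed = integer(0),
                    remaining = integer(0))
  keep <- rep(TRUE, nrow(p))
  note <- function(pass, ok) {
    removed <- sum(keep & !ok)
    keep <- keep & ok
    log <<- rbind(log, data.frame(pass = pass, removed = removed,
                                  remaining = sum(keep)))
    if (verbose) message(sprintf("filter '%s': removed %d, %d remain",
                                 pass, removed, sum(keep)))
    keep
  }
  if (!is.null(origin)) {
    stopifnot(length(origin) == nrow(p))
    wild <- setNames(origin == "wild", p$id)
    ok <- unname(wild[p$id])
    ok_dam <- is.na(p$dam_id) | unname(wild[p$dam_id]) %in% TRUE
    ok_sire <- is.na(p$sire_id) | unname(wild[p$sire_id]) %in% TRUE
    keep <- note("wild origin (self and parents)", ok & ok_dam & ok_sire)
  }
  if (require_length)
    keep <- note("length present", !is.na(p$length_mm))
  if (require_rs)
    keep <- note("reproductive success present", !is.na(p$rs))
  if (require_both_parents)
    keep <- note("offspring with both parents known",
                 p$generation != "offspring" |
                   (!is.na(p$dam_id) & !is.na(p$sire_id)))
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  attr(out, "filter_log") <- log
  out
}

#' Table of mated pairs and their offspring
#'
#' One record per (dam, sire) pair with at least one offspring in the
#' pedigree.  Offspring with only one known parent are included under that
#' pair (the co-parent `NA`) and flagged incomplete.
#'
#' @param p a pedigree.
#' @return Data frame with columns `dam_id`, `sire_id`, `n_offspring`,
#'   `offspring_ids` (list column), `complete`.
#' @export
family_table <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  off <- p[p$generation == "offspring" &
             (!is.na(p$dam_id) | !is.na(p$sire_id)), , drop = FALSE]
  if (!nrow(off))
    return(data.frame(dam_id = character(0), sire_id = character(0),
                      n_offspring = integer(0),
                      offspring_ids = I(list()), complete = logical(0)))
  key <- paste(ifelse(is.na(off$dam_id), "<NA>", off$dam_id),
               ifelse(is.na(off$sire_id), "<NA>", off$sire_id), sep = "\r")
  groups <- split(off$id, key)
  first <- off[!duplicated(key), , drop = FALSE]
  ord <- match(names(groups), key[!duplicated(key)])
  res <- data.frame(dam_id = first$dam_id[ord], sire_id = first$sire_id[ord],
                    n_offspring = lengths(groups), stringsAsFactors = FALSE)
  res$offspring_ids <- I(unname(groups))
  res$complete <- !is.na(res$dam_id) & !is.na(res$sire_id)
  rownames(res) <- NULL
  res
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d parents, %d offspring)\n",
              nrow(x), sum(x$generation == "parent"),
              sum(x$generation == "offspring")))
  tab <- table(x$generation, x$tactic)
  print(tab)
  invisible(x)
}
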