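SEX_CATEGORIES <- c("gonochoric", "androdioecious", "equivocal",
                    "polymorphic", "no_data")

#' Parse a male sex-ratio token
#'
#' Accepts a point value (`"36"`), an interval (`"0-53"`), a one-sided bound
#' (`"<30"`, `"<45"`, `">45"`), the qualitative `"even"`, or an empty/`NA`
#' token for unknown. Footnote markers (`*`) and whitespace are stripped.
#' Values are percentages of males in [0, 100].
#'
#' @param x Character scalar.
#' @return A list with `kind` (`"interval"`, `"even"`, `"unknown"`), `lo`,
#'   `hi`, and openness flags `lo_open`, `hi_open`.
#' @export
parse_male_ratio <- function(x) {
  mk <- function(kind, lo = NA_real_, hi = NA_real_,
                 lo_open = FALSE, hi_open = FALSE)
    list(kind = kind, lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
  if (length(x) != 1L) stop("one ratio token at a time")
  if (is.na(x)) return(mk("unknown"))
  tok <- gsub("[*[:space:]]", "", tolower(as.character(x)))
  if (!nzchar(tok)) return(mk("unknown"))
  if (tok == "even") return(mk("even"))
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("unparseable sex-ratio token: '", x, "'")
    if (v < 0 || v > 100) stop("sex ratio outside [0, 100]: '", x, "'")
    v
  }
  r <-
    if (grepl("^<", tok)) mk("interval", 0, num(sub("^<", "", tok)), hi_open = TRUE)
    else if (grepl("^>", tok)) mk("interval", num(sub("^>", "", tok)), 100, lo_open = TRUE)
    else if (grepl("^[0-9.]+(-|–)[0-9.]+$", tok)) {
      parts <- strsplit(tok, "-|–")[[1]]
      mk("interval", num(parts[1]), num(parts[2]))
    } else mk("interval", num(tok), num(tok))
  if (r$kind == "interval" && r$lo > r$hi)
    stop("sex-ratio interval with lo > hi: '", x, "'")
  r
}

# Band predicates on a parsed ratio (AD band < 30, equivocal 30-45, > 45
# gonochoric). "even" sex ratios sit in the gonochoric band.
ratio_entirely_above_45 <- function(r) {
  r$kind == "even" || (r$kind == "interval" && (r$lo > 45 || (r$lo == 45 && r$lo_open)))
}
ratio_entirely_below_30 <- function(r) {
  r$kind == "interval" && (r$hi < 30 || (r$hi == 30 && r$hi_open))
}
ratio_entirely_at_most_45 <- function(r) {
  r$kind == "interval" && (r$hi < 45 || r$hi == 45)
}
ratio_spans_both_bands <- function(r) {
  r$kind == "interval" && r$lo < 30 && r$hi > 45
}
ratio_unknown <- function(r) r$kind == "unknown"

yn <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return("unknown")
  v <- tolower(trimws(x))
  if (!v %in% c("yes", "no", "unknown")) stop("expected yes/no/unknown, got '", x, "'")
  v
}

new_sex_call <- function(category, rationale, conflict = FALSE, spans = FALSE) {
  structure(list(category = category, rationale = rationale,
                 conflict = conflict, spans = spans),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$category, x$rationale))
  invisible(x)
}

#' Classify one population's sexual system
#'
#' Applies the conservative evidence rules: hermaphrodite evidence (an
#' ovotestis, or confirmed reproduction in isolation) together with a male
#' proportion compatible with at most 45\% assigns androdioecy; without
#' hermaphrodite evidence, more than 45\% male (or a qualitatively even ratio)
#' is gonochoric, under 30\% male is androdioecious, and the 30--45\% band is
#' equivocal. Hermaphrodite evidence conflicting with a >45\% ratio yields an
#' equivocal call with a conflict flag. No usable evidence yields `no_data`.
#'
#' @param male_ratio Ratio token (see [parse_male_ratio()]) or a parsed ratio.
#' @param repro_isolation `"yes"`/`"no"`/`"unknown"` (`yes` should only be
#'   recorded when reproduction with males was also confirmed).
#' @param ovotestis `"yes"`/`"no"`/`"unknown"`.
#' @return A `"sex_call"`: `category`, `rationale`, `conflict`, `spans` (the
#'   last marks an interval covering both the androdioecious and gonochoric
#'   bands with hermaphrodite evidence, promoted to polymorphic at the STU
#'   level).
#' @export
classify_population <- function(male_ratio = NA, repro_isolation = NA,
                                ovotestis = NA) {
  r <- if (is.list(male_ratio)) male_ratio else parse_male_ratio(male_ratio)
  iso <- yn(repro_isolation)
  ovo <- yn(ovotestis)
  herm <- iso == "yes" || ovo == "yes"

  if (herm) {
    ev <- paste(c(if (ovo == "yes") "ovotestis",
                  if (iso == "yes") "reproduction in isolation"), collapse = " + ")
    if (ratio_spans_both_bands(r))
      return(new_sex_call("equivocal",
        paste0("hermaphrodite evidence (", ev,
               ") with a sex-ratio interval spanning <30% and >45%: both systems present"),
        spans = TRUE))
    if (ratio_unknown(r) || ratio_entirely_at_most_45(r))
      return(new_sex_call("androdioecious",
        paste0("hermaphrodite evidence (", ev, ") with male ratio <=45% or unknown")))
    return(new_sex_call("equivocal",
      paste0("conflict: hermaphrodite evidence (", ev, ") but male ratio >45%"),
      conflict = TRUE))
  }
  if (ratio_unknown(r))
    return(new_sex_call("no_data", "no sex-ratio, isolation or histology evidence"))
  if (ratio_entirely_above_45(r))
    return(new_sex_call("gonochoric",
      "male ratio >45% (or even) without hermaphrodite evidence"))
  if (ratio_entirely_below_30(r))
    return(new_sex_call("androdioecious",
      "male ratio <30% without contrary evidence"))
  if (ratio_spans_both_bands(r))
    return(new_sex_call("equivocal",
      "sex-ratio interval spans the androdioecious and gonochoric bands without hermaphrodite evidence"))
  new_sex_call("equivocal", "male ratio in the 30-45% band")
}

#' Aggregate population calls into an STU-level call
#'
#' Both gonochoric and androdioecious population calls within one STU, or a
#' single STU-level ratio interval spanning below 30\% and above 45\% male
#' with hermaphrodite evidence, yield a polymorphic STU. Equivocal and
#' no-data calls never override substantive ones.
#'
#' @param calls A list of `"sex_call"` objects (one per population/record).
#' @return A `"sex_call"`.
#' @export
classify_stu <- function(calls) {
  if (inherits(calls, "sex_call")) calls <- list(calls)
  if (!length(calls)) stop("no population calls supplied")
  stopifnot(all(vapply(calls, inherits, logical(1), "sex_call")))
  cats <- vapply(calls, `[[`, character(1), "category")
  rats <- vapply(calls, `[[`, character(1), "rationale")
  if (any(vapply(calls, `[[`, logical(1), "spans")))
    return(new_sex_call("polymorphic",
      "sex-ratio range spans both bands with hermaphrodite evidence: gonochoric and androdioecious populations"))
  if (all(c("gonochoric", "androdioecious") %in% cats))
    return(new_sex_call("polymorphic",
      "both gonochoric and androdioecious populations observed"))
  for (cat in c("gonochoric", "androdioecious", "equivocal")) {
    if (cat %in% cats)
      return(new_sex_call(cat, paste(unique(rats[cats == cat]), collapse = "; "),
                          conflict = any(vapply(calls, `[[`, logical(1), "conflict"))))
  }
  new_sex_call("no_data", "no population with usable evidence")
}

#' Read a sexual-system evidence table
#'
#' Tab-separated columns: `stu`, `population_id`, `male_ratio`,
#' `repro_isolation`, `ovotestis` (empty cells = unknown).
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_sex_evidence <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("NA", ""), comment.char = "#")
  need <- c("stu", "population_id", "male_ratio", "repro_isolation", "ovotestis")
  if (!all(need %in% names(df)))
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Classify every STU in an evidence table
#'
#' @param evidence Data frame as returned by [read_sex_evidence()].
#' @return Data frame `stu`, `category`, `rationale`, `conflict`, one row per
#'   STU in order of first appearance.
#' @export
classify_sexual_systems <- function(evidence) {
  stus <- unique(evidence$stu)
  rows <- lapply(stus, function(s) {
    sub <- evidence[evidence$stu == s, , drop = FALSE]
    calls <- lapply(seq_len(nrow(sub)), function(i)
      classify_population(sub$male_ratio[i], sub$repro_isolation[i],
                          sub$ovotestis[i]))
    call <- classify_stu(calls)
    data.frame(stu = s, category = call$category, rationale = call$rationale,
               conflict = call$conflict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tabulate sexual-system calls
#'
#' @param calls Data frame from [classify_sexual_systems()], or a character
#'   vector of categories.
#' @return Named integer vector over all five categories, with attribute
#'   `n_with_data` (calls other than `no_data`).
#' @export
tabulate_calls <- function(calls) {
  cats <- if (is.data.frame(calls)) calls$category else as.character(calls)
  bad <- setdiff(unique(cats), SEX_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  counts <- vapply(SEX_CATEGORIES, function(k) sum(cats == k), integer(1))
  attr(counts, "n_with_data") <- sum(counts) - counts[["no_data"]]
  counts
}

#' Bundled Notostraca sexual-system evidence table
#'
#' Literature-compiled sex-ratio, reproduction-in-isolation and ovotestis
#' evidence for the 30 Notostraca STUs, as shipped in `inst/extdata`.
#'
#' @return Data frame of evidence rows.
#' @export
notostraca_evidence <- function() {
  read_sex_evidence(system.file("extdata", "notostraca_sex_evidence.tsv",
                                package = "notosex", mustWork = TRUE))
}
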