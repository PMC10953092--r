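#' Default clinical cohort table dialect
#'
#' Column names and coded values for the packaged clinical staging table:
#' sex coded `f`/`m`, diagnosis mode `Biopsy`/`Necropsy`, fecal occult blood
#' `pos`/`neg`/`n.A`, TNM plus histologic grade as four single digits
#' (T 0-4, N 0-2, M 0-1, grade 1-3), fibrosis `pos`/`neg`, free-text subtype,
#' localization and comorbidities, and an imaging column of `&`-separated
#' modality tags. `n.A` and the empty string both decode to missing; any other
#' unknown code is an error (silent coercion would hide transcription
#' mistakes).
#'
#' @return A list describing expected columns and code maps.
#' @export
cohort_dialect <- function() {
  list(
    columns = c("id", "sex", "age_arrival", "age_death", "diagnosis", "fob",
                "imaging", "t_stage", "n_stage", "m_stage", "grade",
                "fibrosis", "subtype", "localization", "comorbidities"),
    codes = list(
      sex = c(f = "f", m = "m"),
      diagnosis = c(Biopsy = "biopsy", Necropsy = "necropsy"),
      fob = c(pos = "pos", neg = "neg"),
      fibrosis = c(pos = "pos", neg = "neg")
    ),
    ranges = list(t_stage = c(0L, 4L), n_stage = c(0L, 2L),
                  m_stage = c(0L, 1L), grade = c(1L, 3L)),
    missing_tokens = c("n.A", "")
  )
}

decode_coded <- function(x, map, missing_tokens, column) {
  out <- rep(NA_character_, length(x))
  is_missing <- x %in% missing_tokens
  known <- x %in% names(map)
  bad <- !is_missing & !known
  if (any(bad)) {
    stop_bad("unknown code '", x[which(bad)[1]], "' in column '", column,
             "' (row ", which(bad)[1], ")")
  }
  out[known] <- unname(map[x[known]])
  out
}

decode_stage <- function(x, rng, missing_tokens, column) {
  out <- rep(NA_integer_, length(x))
  is_missing <- x %in% missing_tokens
  v <- suppressWarnings(as.integer(x[!is_missing]))
  if (anyNA(v)) {
    stop_bad("non-numeric value in column '", column, "'")
  }
  if (any(v < rng[1] | v > rng[2])) {
    i <- which(v < rng[1] | v > rng[2])[1]
    stop_bad("value ", v[i], " out of range [", rng[1], ", ", rng[2],
             "] in column '", column, "'")
  }
  out[!is_missing] <- v
  out
}

decode_numeric <- function(x, missing_tokens, column) {
  out <- rep(NA_real_, length(x))
  is_missing <- x %in% missing_tokens
  v <- suppressWarnings(as.numeric(x[!is_missing]))
  if (anyNA(v)) stop_bad("non-numeric value in column '", column, "'")
  out[!is_missing] <- v
  out
}

#' Read a clinical cohort table
#'
#' Reads a tab-separated staging/grading table (one row per animal) and decodes
#' it against a [cohort_dialect()]. The imaging column is split on `&` into a
#' list of modality tags.
#'
#' @param path TSV file path.
#' @param dialect Dialect description, default [cohort_dialect()].
#' @return A `data.frame` (one row per animal) with typed columns: character
#'   `id`/`sex`/`diagnosis`/`fob`/`fibrosis`/`subtype`/`localization`/
#'   `comorbidities`, numeric ages, integer stages, and a list column
#'   `imaging` of character tags.
#' @examples
#' cohort <- read_cohort_table(dmmr_example("table1_cohort.tsv"))
#' nrow(cohort)
#' @export
read_cohort_table <- function(path, dialect = cohort_dialect()) {
  raw <- read_tsv_strict(path)
  missing_cols <- setdiff(dialect$columns, names(raw))
  if (length(missing_cols)) {
    stop_bad("cohort table header lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  raw <- raw[dialect$columns]
  if (nrow(raw) == 0L) return(raw)
  mt <- dialect$missing_tokens
  if (anyDuplicated(raw$id)) {
    stop_bad("duplicate animal ID: ", raw$id[duplicated(raw$id)][1])
  }
  out <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  out$sex <- decode_coded(raw$sex, dialect$codes$sex, mt, "sex")
  out$age_arrival <- decode_numeric(raw$age_arrival, mt, "age_arrival")
  out$age_death <- decode_numeric(raw$age_death, mt, "age_death")
  out$diagnosis <- decode_coded(raw$diagnosis, dialect$codes$diagnosis, mt, "diagnosis")
  out$fob <- decode_coded(raw$fob, dialect$codes$fob, mt, "fob")
  out$imaging <- I(lapply(raw$imaging, function(x) {
    if (x %in% mt) return(character(0))
    trimws(strsplit(x, "&", fixed = TRUE)[[1]])
  }))
  for (s in names(dialect$ranges)) {
    out[[s]] <- decode_stage(raw[[s]], dialect$ranges[[s]], mt, s)
  }
  out$fibrosis <- decode_coded(raw$fibrosis, dialect$codes$fibrosis, mt, "fibrosis")
  for (s in c("subtype", "localization", "comorbidities")) {
    v <- raw[[s]]
    v[v %in% mt] <- NA_character_
    out[[s]] <- v
  }
  bad_age <- !is.na(out$age_death) & !is.na(out$age_arrival) &
    out$age_death < out$age_arrival
  if (any(bad_age)) {
    stop_bad("age_death < age_arrival for ", out$id[which(bad_age)[1]])
  }
  out
}

#' Write a clinical cohort table
#'
#' Inverse of [read_cohort_table()]: re-encodes decoded values (missing back to
#' `n.A`, imaging tags joined with `&`) so that write-then-read round-trips.
#'
#' @param cohort Decoded cohort `data.frame`.
#' @param path Output TSV path.
#' @param dialect Dialect description, default [cohort_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path, dialect = cohort_dialect()) {
  enc <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  recode <- function(x, map) {
    out <- rep("n.A", length(x))
    rev_map <- setNames(names(map), unname(map))
    out[!is.na(x)] <- rev_map[x[!is.na(x)]]
    out
  }
  num <- function(x) ifelse(is.na(x), "n.A", format(x, trim = TRUE))
  enc$sex <- recode(cohort$sex, dialect$codes$sex)
  enc$age_arrival <- num(cohort$age_arrival)
  enc$age_death <- num(cohort$age_death)
  enc$diagnosis <- recode(cohort$diagnosis, dialect$codes$diagnosis)
  enc$fob <- recode(cohort$fob, dialect$codes$fob)
  enc$imaging <- vapply(cohort$imaging, function(x) {
    if (!length(x)) "n.A" else paste(x, collapse = " & ")
  }, "")
  for (s in names(dialect$ranges)) enc[[s]] <- num(cohort[[s]])
  enc$fibrosis <- recode(cohort$fibrosis, dialect$codes$fibrosis)
  for (s in c("subtype", "localization", "comorbidities")) {
    enc[[s]] <- ifelse(is.na(cohort[[s]]), "n.A", cohort[[s]])
  }
  write_tsv_strict(enc, path)
}
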