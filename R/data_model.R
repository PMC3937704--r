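#' Normalize striatal volumes by intracranial volume
#'
#' Basal-ganglia volumes are expressed as dimensionless volume/ICV ratios to
#' adjust for head size; cortical thickness is left in mm.
#'
#' @param rawVolumes numeric matrix (subjects x striatal regions) in mm^3,
#'   or a vector.
#' @param icv per-subject intracranial volume in mm^3, strictly positive.
#' @return matrix (or vector) of volume/ICV ratios.
#' @examples
#' normalizeStriatalVolumes(c(s1 = 4000), c(s1 = 1600000))  # 0.0025
#' @export
normalizeStriatalVolumes <- function(rawVolumes, icv) {
  vec <- is.null(dim(rawVolumes))
  m <- as.matrix(rawVolumes)
  icv <- as.numeric(icv)
  if (length(icv) != nrow(m))
    stop("icv must have one value per subject")
  bad <- which(!is.finite(icv) | icv <= 0)
  if (length(bad)) {
    ids <- rownames(m)[bad]
    if (is.null(ids)) ids <- bad
    stop("non-positive ICV for subject(s): ", paste(ids, collapse = ", "))
  }
  if (any(m < 0, na.rm = TRUE)) stop("volumes must be non-negative")
  out <- m / icv
  if (vec) out[, 1] else out
}

.readCsvStrict <- function(path, required, numericCols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (cn in intersect(numericCols, names(df))) {
    raw <- df[[cn]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("parse error in ", basename(path), ": non-numeric value '",
           raw[bad[1]], "' at row ", bad[1], ", column '", cn, "'")
    df[[cn]] <- num
  }
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in ", basename(path))
  df
}

#' Read an aligned cohort from three CSV files
#'
#' Reads `subjects.csv` (subject_id, group, age, sex, education_years,
#' visit_count, optional cag_repeats and motor_score), `morphometry.csv`
#' (subject_id, icv_mm3, one column per region; striatal columns carry the
#' suffix `_vol_mm3` and are divided by ICV on ingest) and `cognition.csv`
#' (subject_id plus the five cognitive scores). The CSV dialect is strict:
#' comma-separated, UTF-8, `.` decimal, mandatory header, empty cell = NA.
#' Subjects present in one file but absent from another are dropped with a
#' message reporting the count.
#'
#' @param subjectsPath,morphometryPath,cognitionPath file paths.
#' @return an [HDCohort-class]; the number of dropped subjects is recorded
#'   in `metadata()$n_dropped`.
#' @export
readCohort <- function(subjectsPath, morphometryPath, cognitionPath) {
  subj <- .readCsvStrict(
    subjectsPath,
    required = c("subject_id", .requiredSubjectCols),
    numericCols = c("age", "education_years", "visit_count",
                    "cag_repeats", "motor_score"))
  morph <- .readCsvStrict(
    morphometryPath,
    required = c("subject_id", "icv_mm3"),
    numericCols = "icv_mm3")
  cog <- .readCsvStrict(
    cognitionPath,
    required = c("subject_id", .cognitionCols),
    numericCols = .cognitionCols)
  for (cn in setdiff(names(morph), "subject_id")) {
    num <- suppressWarnings(as.numeric(morph[[cn]]))
    bad <- which(!is.na(morph[[cn]]) & is.na(num))
    if (length(bad))
      stop("parse error in ", basename(morphometryPath),
           ": non-numeric value at row ", bad[1], ", column '", cn, "'")
    morph[[cn]] <- num
  }

  ids <- Reduce(intersect, list(subj$subject_id, morph$subject_id,
                                cog$subject_id))
  nDropped <- length(unique(c(subj$subject_id, morph$subject_id,
                              cog$subject_id))) - length(ids)
  if (nDropped > 0)
    message(nDropped,
            " subject(s) absent from at least one input file; dropped")
  if (!length(ids)) stop("no subjects shared across the three files")

  subj <- subj[match(ids, subj$subject_id), , drop = FALSE]
  morph <- morph[match(ids, morph$subject_id), , drop = FALSE]
  cog <- cog[match(ids, cog$subject_id), , drop = FALSE]

  icv <- morph$icv_mm3
  regionCols <- setdiff(names(morph), c("subject_id", "icv_mm3"))
  m <- as.matrix(morph[, regionCols, drop = FALSE])
  rownames(m) <- ids
  volCols <- grepl("_vol_mm3$", regionCols)
  rawVolumes <- NULL
  if (any(volCols)) {
    rawVolumes <- m[, volCols, drop = FALSE]
    m[, volCols] <- normalizeStriatalVolumes(rawVolumes, icv)
    colnames(m)[volCols] <- sub("_vol_mm3$", "", colnames(m)[volCols])
  }
  kind <- ifelse(volCols, "volume_ratio", "thickness")

  subj$icv_mm3 <- icv
  HDCohort(m, subj, kind = kind, cognition = cog,
           metadata = list(n_dropped = nDropped,
                           raw_volumes = rawVolumes))
}

#' Write a cohort back to the three-file CSV layout
#'
#' Inverse of [readCohort()]: emits `subjects.csv`, `morphometry.csv`
#' (striatal ratios multiplied back to mm^3 volumes, columns re-suffixed
#' `_vol_mm3`) and `cognition.csv` in `dir`. Numeric values are written at
#' full precision (15 significant digits) so a read/write round trip is
#' value-exact.
#'
#' @param cohort an [HDCohort-class].
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "HDCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  ids <- colnames(cohort)
  subjCols <- intersect(c("group", "age", "sex", "education_years",
                          "visit_count", "cag_repeats", "motor_score"),
                        names(cd))
  subj <- cbind(data.frame(subject_id = ids), cd[, subjCols, drop = FALSE])
  m <- t(morphometry(cohort))
  kind <- regionKind(cohort)
  icv <- cd$icv_mm3
  if (is.null(icv)) icv <- rep(NA_real_, length(ids))
  isVol <- kind[colnames(m)] == "volume_ratio"
  if (any(isVol)) {
    raw <- S4Vectors::metadata(cohort)$raw_volumes
    if (!is.null(raw) && identical(rownames(raw), ids) &&
        ncol(raw) == sum(isVol)) {
      # provenance copy of the untransformed volumes: exact round trip
      m[, isVol] <- raw
    } else {
      m[, isVol] <- m[, isVol, drop = FALSE] * icv
    }
    colnames(m)[isVol] <- paste0(colnames(m)[isVol], "_vol_mm3")
  }
  morph <- cbind(data.frame(subject_id = ids, icv_mm3 = icv),
                 as.data.frame(m))
  cogCols <- intersect(.cognitionCols, names(cd))
  cog <- cbind(data.frame(subject_id = ids), cd[, cogCols, drop = FALSE])

  paths <- file.path(dir, c("subjects.csv", "morphometry.csv",
                            "cognition.csv"))
  utils::write.csv(.fmtNumeric(subj), paths[1], row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(.fmtNumeric(morph), paths[2], row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(.fmtNumeric(cog), paths[3], row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(paths)
}

# format numeric columns with 17 significant digits so that
# as.numeric(format(x)) == x bit-exactly (doubles round-trip at 17 digits)
.fmtNumeric <- function(df) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) {
      v <- df[[cn]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      df[[cn]] <- s
    }
  }
  df
}
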