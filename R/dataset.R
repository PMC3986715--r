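#' Construct a formulation dataset
#'
#' A formulation dataset pairs compositions with their dissolution
#' profiles on one shared sampling schedule — the training corpus for the
#' surrogate model.
#'
#' @param id Character vector of unique record labels (e.g. "SAL001").
#' @param composition Numeric matrix (n x 4) of factor levels, columns in
#'   the order methocel_mg, xanthan_mg, carbopol_mg, surelease_pct.
#' @param release Numeric matrix (n x length(times_h)) of percent
#'   released, or `NULL` for a design without measured profiles.
#' @param times_h Shared sampling schedule, hours.
#' @param check Enforce the composition domain (see [formulation()]).
#' @return An object of class `formulation_dataset` with fields `id`,
#'   `composition`, `release`, `times_h`.
#' @export
formulation_dataset <- function(id, composition, release = NULL,
                                times_h = canonical_times(), check = TRUE) {
  id <- as.character(id)
  composition <- as.matrix(composition)
  storage.mode(composition) <- "double"
  if (ncol(composition) != 4L) stopf("composition must have 4 columns")
  colnames(composition) <- .factor_names
  n <- nrow(composition)
  if (length(id) != n) stopf("ids (%d) and compositions (%d) differ in length",
                             length(id), n)
  if (anyDuplicated(id)) {
    stopf("duplicate record id: %s", id[anyDuplicated(id)])
  }
  for (i in seq_len(n)) {
    f <- try(formulation(composition[i, 1], composition[i, 2],
                         composition[i, 3], composition[i, 4], check = check),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      stopf("record %s: %s", id[i],
            sub("^Error : ", "", attr(f, "condition")$message))
    }
  }
  times_h <- as.numeric(times_h)
  if (!is.null(release)) {
    release <- as.matrix(release)
    storage.mode(release) <- "double"
    if (nrow(release) != n || ncol(release) != length(times_h)) {
      stopf("release must be %d x %d", n, length(times_h))
    }
    for (i in seq_len(n)) {
      p <- try(dissolution_profile(release[i, ], times_h), silent = TRUE)
      if (inherits(p, "try-error")) {
        stopf("record %s: %s", id[i],
              sub("^Error : ", "", attr(p, "condition")$message))
      }
    }
    colnames(release) <- profile_colnames(times_h)
  }
  structure(list(id = id, composition = composition, release = release,
                 times_h = times_h),
            class = "formulation_dataset")
}

#' @export
print.formulation_dataset <- function(x, ...) {
  cat(sprintf("Formulation dataset: %d records, %s\n", nrow(x$composition),
              if (is.null(x$release)) "no dissolution profiles" else
                sprintf("profiles at %s h", paste(x$times_h, collapse = ", "))))
  invisible(x)
}

#' @export
length.formulation_dataset <- function(x) nrow(x$composition)

#' Extract one record's profile
#'
#' @param dataset A [formulation_dataset()].
#' @param i Record index or id.
#' @return A [dissolution_profile()].
#' @export
dataset_profile <- function(dataset, i) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  if (is.null(dataset$release)) stopf("dataset has no dissolution profiles")
  if (is.character(i)) i <- match(i, dataset$id)
  dissolution_profile(dataset$release[i, ], dataset$times_h, check = FALSE)
}

# Profile column names encode the sampling time: "t<hours>h".
profile_colnames <- function(times_h) paste0("t", format(times_h, trim = TRUE,
                                                         scientific = FALSE), "h")

parse_profile_colnames <- function(nms) {
  m <- regmatches(nms, regexec("^t([0-9]+\\.?[0-9]*)h$", nms))
  ok <- lengths(m) == 2L
  times <- rep(NA_real_, length(nms))
  times[ok] <- as.numeric(vapply(m[ok], `[`, "", 2L))
  times
}

#' Read a formulation dataset from a delimited-text file
#'
#' The file format is comma-delimited with a header line naming the id
#' column, the four composition columns (`methocel_mg`, `xanthan_mg`,
#' `carbopol_mg`, `surelease_pct`) and one `t<hours>h` column per
#' sampling time (e.g. `t1h`, `t12h`). Sampling times are parsed from the
#' header. A file with no profile columns is read as a bare design.
#'
#' @param path Path to the CSV file.
#' @param check Enforce the composition domain; out-of-domain rows are
#'   errors naming the offending record.
#' @return A [formulation_dataset()].
#' @export
read_dataset <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"id" %in% names(df)) stopf("dataset file is missing column 'id'")
  missing_cols <- setdiff(.factor_names, names(df))
  if (length(missing_cols)) {
    stopf("dataset file is missing column '%s'", missing_cols[1])
  }
  other <- setdiff(names(df), c("id", .factor_names))
  times <- parse_profile_colnames(other)
  if (any(is.na(times)) && length(other)) {
    stopf("unrecognized column '%s' (profile columns are named t<hours>h)",
          other[which(is.na(times))[1]])
  }
  ord <- order(times)
  prof_cols <- other[ord]
  times <- times[ord]
  for (cn in c(.factor_names, prof_cols)) {
    v <- df[[cn]]
    if (!is.numeric(v) && nrow(df) > 0L) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stopf("record %s: non-numeric value '%s' in column %s",
            df$id[bad], v[bad], cn)
      }
  }
  release <- if (length(prof_cols)) as.matrix(df[, prof_cols, drop = FALSE])
             else NULL
  formulation_dataset(df$id, as.matrix(df[, .factor_names]),
                      release = release,
                      times_h = if (length(prof_cols)) times
                                else canonical_times(),
                      check = check)
}

#' Write a formulation dataset to a delimited-text file
#'
#' Inverse of [read_dataset()]: the numeric payload round-trips exactly
#' (values are written with full double precision).
#'
#' @param dataset A [formulation_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "formulation_dataset"))
  df <- data.frame(id = dataset$id, stringsAsFactors = FALSE)
  comp <- dataset$composition
  for (j in seq_along(.factor_names)) df[[.factor_names[j]]] <- comp[, j]
  if (!is.null(dataset$release)) {
    rel <- dataset$release
    cn <- profile_colnames(dataset$times_h)
    for (j in seq_along(cn)) df[[cn[j]]] <- rel[, j]
  }
  # 17 significant digits preserve doubles exactly across a round trip
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 30-run central composite study design
#'
#' The fixed four-factor central composite design used as the study's
#' formulation plan: 16 factorial runs, 8 axial runs and 6 center-point
#' replicates, ids SAL001 to SAL030 in manufacture order.
#'
#' @return A [formulation_dataset()] of the 30 compositions (no
#'   dissolution profiles).
#' @examples
#' d <- study_design()
#' d$composition[1, ]
#' @export
study_design <- function() {
  m <- matrix(c(
    120, 50, 10, 12,
     60, 50, 10, 12,
     60, 50, 10,  4,
     60, 50, 20, 12,
     90, 75, 15, 16,
     60, 50, 10, 20,
     90, 25, 15, 16,
     30, 75, 15, 16,
     60, 50, 10, 12,
     90, 75,  5,  8,
      0, 50, 10, 12,
     30, 25,  5, 16,
     60, 50, 10, 12,
     30, 25, 15,  8,
     60, 50, 10, 12,
     60, 100, 10, 12,
     90, 75,  5, 16,
     30, 25, 15, 16,
     90, 25,  5,  8,
     90, 75, 15,  8,
     30, 75,  5, 16,
     30, 25,  5,  8,
     30, 75,  5,  8,
     90, 25, 15,  8,
     60, 50,  0, 12,
     90, 25,  5, 16,
     60,  0, 10, 12,
     60, 50, 10, 12,
     60, 50, 10, 12,
     30, 75, 15,  8), ncol = 4, byrow = TRUE)
  formulation_dataset(sprintf("SAL%03d", 1:30), m)
}
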