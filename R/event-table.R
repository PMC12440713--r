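# Event-table I/O.
#
# Canonical CSV dialect (one row per dose or observation event):
#   ID, TIME, AMT, DV, EVID, MDV, WT, AGE, SEX [, BLQ]
# EVID 1 = dose (AMT in mg, DV = "."), EVID 0 = observation (DV in mg/L,
# AMT = "."). MDV = 1 marks a missing/excluded DV. Times in hours since
# first dose; dot decimal; header required. Lines starting with '#' are
# metadata comments. An observation sharing a time with a dose is a
# predose (trough) sample and sorts before the dose row. The optional BLQ
# column flags observations below the assay LLOQ.

ET_COLUMNS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT", "AGE", "SEX")

validate_event_table <- function(x) {
  miss <- setdiff(ET_COLUMNS, names(x))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  bad_evid <- which(!x$EVID %in% c(0L, 1L))
  if (length(bad_evid))
    stop("unsupported EVID at row ", bad_evid[1],
         " (only 0 = observation, 1 = dose)")
  bad_amt <- which(x$EVID == 1L & (is.na(x$AMT) | x$AMT <= 0))
  if (length(bad_amt))
    stop("dose row with missing or non-positive AMT at row ", bad_amt[1])
  bad_dv <- which(!is.na(x$DV) & x$DV < 0)
  if (length(bad_dv))
    stop("negative DV at row ", bad_dv[1])
  bad_t <- which(is.na(x$TIME) | x$TIME < 0)
  if (length(bad_t))
    stop("missing or negative TIME at row ", bad_t[1])
  for (id in unique(x$ID)) {
    tt <- x$TIME[x$ID == id]
    if (is.unsorted(tt))
      stop("non-monotone TIME within subject ", id)
  }
  bad_mdv <- which(x$EVID == 0L & is.na(x$DV) & x$MDV != 1L)
  if (length(bad_mdv))
    stop("observation with missing DV but MDV != 1 at row ", bad_mdv[1])
  invisible(x)
}

#' Read an event table from CSV
#'
#' Parses the package's NONMEM-style CSV dialect (see the package
#' vignette): columns `ID, TIME, AMT, DV, EVID, MDV, WT, AGE, SEX` plus an
#' optional `BLQ` flag, dot decimal, `"."` for missing values, `#`-prefixed
#' comment lines allowed. Validation is strict: unknown columns, `EVID`
#' other than 0/1, negative `AMT`/`DV` or non-monotone times within a
#' subject raise an error naming the offending row.
#'
#' @param path file path.
#' @return A `pb_event_table` data frame.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", comment.char = "#",
                  check.names = FALSE)
  extra <- setdiff(names(raw), c(ET_COLUMNS, "BLQ"))
  if (length(extra))
    stop("unknown column(s) in event table: ", paste(extra, collapse = ", "))
  num <- function(v) {
    v[v == "."] <- NA_character_
    suppressWarnings(as.numeric(v))
  }
  x <- data.frame(ID = as.integer(num(raw$ID)), TIME = num(raw$TIME),
                  AMT = num(raw$AMT), DV = num(raw$DV),
                  EVID = as.integer(num(raw$EVID)),
                  MDV = as.integer(num(raw$MDV)),
                  WT = num(raw$WT), AGE = num(raw$AGE),
                  SEX = as.integer(num(raw$SEX)))
  if ("BLQ" %in% names(raw)) x$BLQ <- as.integer(num(raw$BLQ))
  validate_event_table(x)
  class(x) <- c("pb_event_table", "data.frame")
  x
}

#' Write an event table to CSV
#'
#' Inverse of [read_event_table()]; numbers are written with full
#' precision (`%.17g`) so that a write/read round trip reproduces the
#' table exactly. Optional `header_comments` (e.g. the generating seed)
#' are emitted as `#` lines before the header.
#'
#' @param x a `pb_event_table` (or conforming data frame).
#' @param path output file path.
#' @param header_comments character vector of metadata lines.
#' @export
write_event_table <- function(x, path, header_comments = NULL) {
  validate_event_table(x)
  cols <- c(ET_COLUMNS, intersect("BLQ", names(x)))
  fmt <- function(v) {
    out <- vapply(v, function(z) {
      if (is.na(z)) "." else sprintf("%.17g", as.numeric(z))
    }, character(1))
    out
  }
  mat <- vapply(cols, function(cl) fmt(x[[cl]]), character(nrow(x)))
  if (nrow(x) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, cols))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(mat, 1L, paste, collapse = ","), con)
  invisible(path)
}

# Split an event table into per-subject records used by the estimation and
# diagnostics code. Observations kept for fitting have EVID 0 and MDV 0.
subject_records <- function(data) {
  validate_event_table(data)
  lapply(split(seq_len(nrow(data)), data$ID), function(ix) {
    d <- data[ix, ]
    obs <- d[d$EVID == 0L & d$MDV == 0L, ]
    list(id = d$ID[1], weight = d$WT[1], age = d$AGE[1], sex = d$SEX[1],
         obs_time = obs$TIME, dv = obs$DV,
         dose_time = d$TIME[d$EVID == 1L], dose_amt = d$AMT[d$EVID == 1L])
  })
}
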