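## Reading and writing online pen recordings.
##
## Canonical dialect: UTF-8 TSV with header `t_ms x y p az alt pen_down`,
## optional leading comment lines `# subject_id=...` / `# label=...`,
## pen_down coded 0/1.  A shim for headerless space-separated exports with
## a configurable column order is provided via penDialect().

CANONICAL_COLUMNS <- c("t_ms", "x", "y", "p", "az", "alt", "pen_down")

#' Describe a pen-stream file dialect
#'
#' @param sep field separator (`"\t"` canonical; `""` = any whitespace).
#' @param header does the file carry a header row?
#' @param columns column order for headerless files; names from
#'   `t_ms, x, y, p, az, alt, pen_down` (`t_ms` may be omitted, in which
#'   case time is synthesized as index / sampleRateHz).
#' @param sampleRateHz rate used to synthesize timestamps when absent.
#' @return A list describing the dialect, for [readPenStream()].
#' @export
penDialect <- function(sep = "\t", header = TRUE, columns = CANONICAL_COLUMNS,
                       sampleRateHz = 125) {
  stopifnot(all(columns %in% CANONICAL_COLUMNS))
  list(sep = sep, header = header, columns = columns,
       sampleRateHz = sampleRateHz)
}

#' Read an online pen recording
#'
#' @param path file path.
#' @param dialect a [penDialect()] descriptor.
#' @return A validated [PenStream-class].
#' @export
readPenStream <- function(path, dialect = penDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isComment <- startsWith(lines, "#")
  meta <- c(subject_id = "anonymous", label = "unknown")
  for (cm in lines[isComment]) {
    kv <- regmatches(cm, gregexpr("(subject_id|label)=\\S+", cm))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[p[1]] <- p[2]
    }
  }
  body <- lines[!isComment]
  lineNo <- seq_along(lines)[!isComment]
  if (dialect$header) {
    cols <- strsplit(body[1], if (nzchar(dialect$sep)) dialect$sep else "[ \t]+")[[1]]
    if (!all(cols %in% CANONICAL_COLUMNS))
      stop("unknown columns in header: ",
           paste(setdiff(cols, CANONICAL_COLUMNS), collapse = ", "))
    body <- body[-1]; lineNo <- lineNo[-1]
  } else cols <- dialect$columns
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    df <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                     p = numeric(0), az = numeric(0), alt = numeric(0),
                     penDown = logical(0))
    return(PenStream(df, subjectId = meta[["subject_id"]],
                     label = meta[["label"]],
                     sampleRateHz = dialect$sampleRateHz))
  }
  parts <- strsplit(body, if (nzchar(dialect$sep)) dialect$sep else "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    bad <- which(nf != length(cols))[1]
    stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                 lineNo[bad], path, length(cols), nf[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(cols), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 lineNo[bad], path))
  }
  colnames(m) <- cols
  needed <- setdiff(CANONICAL_COLUMNS, "t_ms")
  if (!all(needed %in% cols))
    stop("dialect lacks required columns: ",
         paste(setdiff(needed, cols), collapse = ", "))
  t <- if ("t_ms" %in% cols) m[, "t_ms"] / 1000
       else (seq_len(nrow(m)) - 1) / dialect$sampleRateHz
  if (nrow(m) > 1 && any(diff(t) <= 0))
    stop("validation error: time is not strictly increasing in ", path)
  df <- data.frame(t = t, x = m[, "x"], y = m[, "y"], p = m[, "p"],
                   az = m[, "az"], alt = m[, "alt"],
                   penDown = m[, "pen_down"] != 0)
  PenStream(df, subjectId = meta[["subject_id"]], label = meta[["label"]],
            sampleRateHz = dialect$sampleRateHz)
}

#' Write an online pen recording in the canonical TSV dialect
#'
#' Numeric fields are written with 15 significant digits, which round-trips
#' double precision through [readPenStream()].
#'
#' @param stream a [PenStream-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePenStream <- function(stream, path) {
  validObject(stream)
  s <- penSamples(stream)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s label=%s", subjectId(stream),
                     penLabel(stream)), con)
  writeLines(paste(CANONICAL_COLUMNS, collapse = "\t"), con)
  if (nrow(s)) {
    num <- function(v) sprintf("%.15g", v)
    writeLines(paste(num(s$t * 1000), num(s$x), num(s$y), num(s$p),
                     num(s$az), num(s$alt), as.integer(s$penDown),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Split a stream into maximal runs of constant pen state
#'
#' @param stream a [PenStream-class].
#' @return data.frame with columns `state` (`"down"`/`"up"`), `start`,
#'   `end` (1-based sample indices, inclusive), covering every sample
#'   exactly once.
#' @export
splitPenStates <- function(stream) {
  pd <- penSamples(stream)$penDown
  if (!length(pd))
    return(data.frame(state = character(0), start = integer(0),
                      end = integer(0)))
  r <- rle(pd)
  end <- cumsum(r$lengths)
  data.frame(state = ifelse(r$values, "down", "up"),
             start = c(1L, head(end, -1) + 1L), end = end,
             stringsAsFactors = FALSE)
}
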