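#' Write / read a trial table as CSV
#'
#' The dialect is `pid,week,age,arm,y,observed` with a signed integer week
#' and an empty `y` field for masked cells (`observed = 0`), so masked
#' values do not leak into exported data.
#'
#' @param table a trial table.
#' @param path file path.
#' @return `path` invisibly (writer); the trial table (reader), with `NA`
#'   outcome on masked rows.
#' @export
write_trial <- function(table, path) {
  out <- table[, c("pid", "week", "age", "arm", "y", "observed")]
  out$y[out$observed == 0L] <- NA_real_
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pid", "week", "age", "arm", "y", "observed")
  if (!all(need %in% names(tab)))
    stop("read_trial: expected columns ", paste(need, collapse = ","))
  tab$week <- as.integer(tab$week)
  tab$arm <- as.integer(tab$arm)
  tab$observed <- as.integer(tab$observed)
  tab[need]
}

#' Write / read a configuration object as JSON
#'
#' Flat key/value serialization of [gen_config()], [miss_config()] or
#' [impute_config()] objects; the class is stored alongside the fields so
#' [read_config()] can rebuild through the right constructor (re-running
#' its validity checks).
#'
#' @param config a `gen_config`, `miss_config` or `impute_config`.
#' @param path file path.
#' @return `path` invisibly (writer); the configuration object (reader).
#' @export
write_config <- function(config, path) {
  cls <- class(config)[1]
  if (!cls %in% c("gen_config", "miss_config", "impute_config"))
    stop("write_config: unsupported configuration class ", cls)
  fields <- unclass(config)
  fields <- fields[!vapply(fields, is.null, TRUE)]
  ## named atomic vectors (e.g. centers) must serialize as JSON objects
  nv <- vapply(fields, function(x) is.atomic(x) && !is.null(names(x)), TRUE)
  fields[nv] <- lapply(fields[nv], as.list)
  jsonlite::write_json(c(list(.class = cls), fields), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  maker <- switch(cls,
                  gen_config = gen_config,
                  miss_config = miss_config,
                  impute_config = impute_config,
                  stop("read_config: unsupported configuration class ", cls))
  if (identical(cls, "miss_config") && !is.null(x$centers))
    x$centers <- unlist(x$centers)
  do.call(maker, x)
}
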