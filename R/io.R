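#' Write a trajectory to a columnar text file
#'
#' Plain tab-separated text with a commented header (format version, seed,
#' landscape label, config digest): diffable, loss-free at 9 significant
#' digits, and importable by anything that reads TSV.
#'
#' @param trajectory Trajectory tibble (columns `replica`, `step`, `time`,
#'   `ion`, `species`, `x`, `y`, `z`; missing `replica`/`step` filled
#'   with 1).
#' @param path Output file path.
#' @param seed Seed recorded in the header.
#' @param landscape Landscape label recorded in the header.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path, seed = NA, landscape = "custom") {
  tr <- tibble::as_tibble(trajectory)
  if (!("replica" %in% names(tr))) tr$replica <- 1L
  if (!("step" %in% names(tr))) tr$step <- 1L
  cols <- c("replica", "step", "time", "ion", "species", "x", "y", "z")
  missing <- setdiff(cols, names(tr))
  if (length(missing) > 0)
    stop("trajectory lacks columns: ", paste(missing, collapse = ", "))
  tr <- tr[, cols]
  digest <- sum(as.integer(charToRaw(paste(format(c(tr$time[1], nrow(tr))),
                                           collapse = "")))) %% 99991
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# format: ion-trajectory v1",
               paste0("# seed: ", seed),
               paste0("# landscape: ", landscape),
               paste0("# digest: ", digest),
               paste(cols, collapse = "\t")), con)
  body <- apply(cbind(tr$replica, tr$step, format(tr$time, digits = 9,
                                                  trim = TRUE),
                      tr$ion, tr$species,
                      format(tr$x, digits = 9, trim = TRUE),
                      format(tr$y, digits = 9, trim = TRUE),
                      format(tr$z, digits = 9, trim = TRUE)),
                1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a columnar trajectory file
#'
#' Strict by default: the header must be present and every record must have
#' exactly the declared columns; the first malformed line is named in the
#' error. With `lenient = TRUE`, extra trailing columns (foreign dialects)
#' are dropped with a warning.
#'
#' @param path File path.
#' @param lenient Accept (and ignore) extra trailing columns.
#' @return A trajectory tibble; header fields are kept as attributes
#'   `seed`, `landscape`, `digest`.
#' @export
read_trajectory <- function(path, lenient = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !grepl("^# format: ion-trajectory",
                                 lines[1]))
    stop("parse error at line 1: missing 'ion-trajectory' header")
  meta <- sub("^# *", "", lines[hdr])
  get_meta <- function(key) {
    m <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(m) == 0) NA_character_ else trimws(sub(".*?:", "", m[1]))
  }
  col_line <- hdr[length(hdr)] + 1
  cols <- strsplit(lines[col_line], "\t")[[1]]
  expected <- c("replica", "step", "time", "ion", "species", "x", "y", "z")
  if (!identical(cols[seq_along(expected)], expected))
    stop("parse error at line ", col_line, ": unexpected column header")
  body <- lines[-seq_len(col_line)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(cols))) {
    bad <- which(nfield != length(cols))[1]
    if (!lenient || any(nfield < length(expected)))
      stop("parse error at line ", col_line + bad, ": expected ",
           length(cols), " fields, found ", nfield[bad])
  }
  if (lenient && any(nfield > length(expected)))
    warning("ignoring extra trailing columns (lenient mode)")
  m <- do.call(rbind, lapply(parts, `[`, seq_along(expected)))
  out <- tibble::tibble(replica = as.integer(m[, 1]),
                        step = as.integer(m[, 2]),
                        time = as.numeric(m[, 3]),
                        ion = as.integer(m[, 4]),
                        species = m[, 5],
                        x = as.numeric(m[, 6]),
                        y = as.numeric(m[, 7]),
                        z = as.numeric(m[, 8]))
  if (anyNA(out$time) || anyNA(out$x) || anyNA(out$y) || anyNA(out$z)) {
    bad <- which(is.na(out$time) | is.na(out$x) | is.na(out$y) |
                   is.na(out$z))[1]
    stop("parse error at line ", col_line + bad, ": non-numeric field")
  }
  attr(out, "seed") <- get_meta("seed")
  attr(out, "landscape") <- get_meta("landscape")
  attr(out, "digest") <- get_meta("digest")
  out
}

#' Write a PMF grid as a dense text matrix
#'
#' Header records the axes, temperature, offset convention and convergence
#' residual; masked (unsampled) bins are written as NA.
#'
#' @param grid A `pmf_grid`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pmf_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pmf_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  ax_line <- function(i) {
    a <- grid$axes[[i]]
    sprintf("# axis%d: min=%g max=%g bin=%g", i, a$min, a$max, a$bin)
  }
  writeLines(c("# format: pmf-grid v1",
               vapply(seq_len(grid$dim), ax_line, character(1)),
               paste0("# temperature: ", grid$temperature),
               "# offset: min of sampled bins = 0",
               paste0("# residual: ", format(grid$residual, digits = 6)),
               paste0("# converged: ", grid$converged)), con)
  v <- grid$values
  out_m <- if (grid$dim == 1) matrix(v, nrow = 1) else t(v)
  utils::write.table(format(out_m, digits = 9, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a PMF grid text matrix
#'
#' @param path File path written by [write_pmf_grid()].
#' @return A `pmf_grid`.
#' @export
read_pmf_grid <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# format: pmf-grid", lines[1]))
    stop("parse error at line 1: missing 'pmf-grid' header")
  hdr <- lines[grep("^#", lines)]
  ax <- list()
  for (i in 1:2) {
    m <- grep(sprintf("^# axis%d:", i), hdr, value = TRUE)
    if (length(m) == 0) next
    g <- as.numeric(sub(".*min=([-0-9.eE+]+) max=([-0-9.eE+]+) bin=([-0-9.eE+]+)",
                        "\\1 \\2 \\3", m[1]) |> strsplit(" ") |> unlist())
    ax[[i]] <- list(min = g[1], max = g[2], bin = g[3],
                    mids = seq(g[1] + g[3] / 2, g[2] - g[3] / 2, by = g[3]))
  }
  temp <- as.numeric(trimws(sub(".*:", "",
                                grep("^# temperature", hdr, value = TRUE)[1])))
  resid <- as.numeric(trimws(sub(".*:", "",
                                 grep("^# residual", hdr, value = TRUE)[1])))
  conv <- as.logical(trimws(sub(".*:", "",
                                grep("^# converged", hdr, value = TRUE)[1])))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parse_row <- function(x) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    ok <- x != "NA"
    out[ok] <- as.numeric(x[ok])
    out
  }
  m <- do.call(rbind, lapply(strsplit(body, "\t"), parse_row))
  if (length(ax) == 1) {
    if (nrow(m) != 1 || ncol(m) != length(ax[[1]]$mids))
      stop("matrix dimensions do not match the axis specification")
    new_pmf_grid(as.numeric(m[1, ]), ax, temp, NA_integer_, resid, conv,
                 source = "file")
  } else {
    vals <- t(m)  # file rows follow axis 2
    if (nrow(vals) != length(ax[[1]]$mids) ||
        ncol(vals) != length(ax[[2]]$mids))
      stop("matrix dimensions do not match the axis specification")
    new_pmf_grid(vals, ax, temp, NA_integer_, resid, conv, source = "file")
  }
}

#' Write a JSON analysis report
#'
#' Serialises block reports, asymmetry reports, minima tables or plain
#' lists to readable JSON.
#'
#' @param x A `block_report`, `asymmetry_report`, tibble or list.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, c("block_report", "asymmetry_report"))) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
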