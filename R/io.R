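#' Write a trajectory to a text format
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`xyz`}{Extended XYZ: per frame an atom count line, then a comment
#'     line `box Lx Ly Lz time t units u wrapped w` carrying the periodic box
#'     and metadata, then `type x y z` rows.}
#'   \item{`lammps-dump`}{LAMMPS-style dump with orthogonal box bounds and
#'     `ATOMS id type x y z` columns. Atom ids are written 1-based and sorted
#'     on read.}
#' }
#'
#' @param traj an `md_trajectory`
#' @param path output file path
#' @param format `"xyz"` or `"lammps-dump"`
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "lammps-dump")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  types <- traj$topology$bead_types
  type_ids <- as.integer(factor(types, levels = unique(types)))
  for (fr in traj$frames) {
    n <- nrow(fr$positions)
    if (format == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf("box %.10g %.10g %.10g time %.10g units %s wrapped %d",
                         fr$box[1], fr$box[2], fr$box[3], as.numeric(fr$time),
                         traj$metadata$units,
                         as.integer(isTRUE(traj$metadata$wrapped))), con)
      writeLines(sprintf("%s %.10g %.10g %.10g", types,
                         fr$positions[, 1], fr$positions[, 2], fr$positions[, 3]),
                 con)
    } else {
      writeLines(c("ITEM: TIMESTEP", sprintf("%.10g", as.numeric(fr$time)),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf("0 %.10g", fr$box[1]),
                   sprintf("0 %.10g", fr$box[2]),
                   sprintf("0 %.10g", fr$box[3]),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(sprintf("%d %d %.10g %.10g %.10g", seq_len(n), type_ids,
                         fr$positions[, 1], fr$positions[, 2], fr$positions[, 3]),
                 con)
    }
  }
  invisible(path)
}

#' Read a trajectory from a text format
#'
#' See [write_trajectory()] for the supported dialects. The reader validates
#' that every frame carries the same bead count and refuses malformed or
#' truncated frames rather than silently dropping them.
#'
#' @param path input file
#' @param format `"xyz"` or `"lammps-dump"`
#' @param topology optional `chain_topology` describing chain connectivity
#'   (neither format stores bonds); if omitted, a bond-less placeholder
#'   topology is attached and connectivity-dependent analyses will refuse it
#' @return an `md_trajectory`
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps-dump"),
                            topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("trajectory format error: empty file")
  if (format == "xyz") res <- parse_xyz(lines) else res <- parse_dump(lines)
  nb <- nrow(res$frames[[1]]$positions)
  if (is.null(topology)) topology <- topology_unbonded(nb)
  if (topology$n_beads != nb)
    stop("topology bead count (", topology$n_beads,
         ") does not match file bead count (", nb, ")")
  md_trajectory(topology, res$frames, units = res$units, wrapped = res$wrapped)
}

parse_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  units <- "real"; wrapped <- TRUE
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0)
      stop("trajectory format error: expected atom count at line ", i)
    if (i + 1L + n > length(lines))
      stop("trajectory format error: truncated frame at line ", i)
    hdr <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    kv <- function(key, m = 1) {
      p <- match(key, hdr)
      if (is.na(p)) return(NULL)
      hdr[(p + 1):(p + m)]
    }
    box <- as.numeric(kv("box", 3))
    if (length(box) != 3 || anyNA(box))
      stop("trajectory format error: XYZ comment line must carry 'box Lx Ly Lz'")
    tm <- as.numeric(kv("time")); if (length(tm) == 0 || is.na(tm)) tm <- length(frames)
    u <- kv("units"); if (!is.null(u)) units <- u
    w <- kv("wrapped"); if (!is.null(w)) wrapped <- w == "1"
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("trajectory format error: malformed atom row in frame starting at line ", i)
    pos <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (anyNA(pos)) stop("trajectory format error: non-numeric coordinate")
    frames[[length(frames) + 1L]] <- md_frame(pos, box, tm)
    i <- i + 2L + n
  }
  check_consistent_counts(frames)
  list(frames = frames, units = units, wrapped = wrapped)
}

parse_dump <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("trajectory format error: expected ITEM: TIMESTEP at line ", i)
    tm <- as.numeric(lines[i + 1L])
    if (!startsWith(lines[i + 2L], "ITEM: NUMBER OF ATOMS"))
      stop("trajectory format error: expected ITEM: NUMBER OF ATOMS at line ", i + 2L)
    n <- as.integer(lines[i + 3L])
    if (is.na(n) || n <= 0) stop("trajectory format error: bad atom count")
    if (!startsWith(lines[i + 4L], "ITEM: BOX BOUNDS"))
      stop("trajectory format error: expected ITEM: BOX BOUNDS")
    bb <- t(vapply(strsplit(trimws(lines[(i + 5L):(i + 7L)]), "\\s+"),
                   function(z) as.numeric(z[1:2]), numeric(2)))
    box <- bb[, 2] - bb[, 1]
    if (anyNA(box) || any(box <= 0)) stop("trajectory format error: bad box bounds")
    acol <- lines[i + 8L]
    if (!startsWith(acol, "ITEM: ATOMS"))
      stop("trajectory format error: expected ITEM: ATOMS")
    cols <- strsplit(sub("ITEM: ATOMS\\s*", "", acol), "\\s+")[[1]]
    need <- c("id", "x", "y", "z")
    if (!all(need %in% cols))
      stop("trajectory format error: dump must contain columns id x y z")
    if (i + 8L + n > length(lines))
      stop("trajectory format error: truncated frame at line ", i)
    rows <- strsplit(trimws(lines[(i + 9L):(i + 8L + n)]), "\\s+")
    if (any(lengths(rows) != length(cols)))
      stop("trajectory format error: malformed atom row")
    m <- matrix(as.numeric(unlist(rows)), ncol = length(cols), byrow = TRUE)
    if (anyNA(m)) stop("trajectory format error: non-numeric field")
    ord <- order(m[, match("id", cols)])
    pos <- m[ord, match(c("x", "y", "z"), cols), drop = FALSE]
    frames[[length(frames) + 1L]] <- md_frame(pos, box, tm)
    i <- i + 9L + n
  }
  check_consistent_counts(frames)
  list(frames = frames, units = "real", wrapped = TRUE)
}

check_consistent_counts <- function(frames) {
  nb <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(nb)) != 1)
    stop("trajectory format error: inconsistent bead counts across frames (",
         paste(unique(nb), collapse = ", "), ")")
  invisible(TRUE)
}

#' Write analysis records to a delimited text file
#'
#' Writes a data frame as comma-separated text with a header row, preceded by
#' `#`-prefixed metadata lines. Column order follows `columns`, so output is
#' deterministic; numeric values round-trip through [read_records()] at full
#' double precision.
#'
#' @param records data frame of records
#' @param path output path
#' @param columns required column names, in output order (schema); an error is
#'   raised if any is missing from `records`
#' @param meta named list written as `# key: value` header lines
#' @export
write_records <- function(records, path, columns = names(records), meta = list()) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  missing_cols <- setdiff(columns, names(records))
  if (length(missing_cols) > 0)
    stop("records do not conform to schema; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  utils::write.csv(records[, columns, drop = FALSE], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read records written by [write_records()]
#' @param path input path
#' @return data frame; `#` metadata lines are returned in attribute `"meta"`
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^#\\s*", "", meta_lines)
  df
}
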