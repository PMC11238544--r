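#' Read a PLUMED COLVAR file
#'
#' Parses the whitespace-separated numeric table below the `#! FIELDS`
#' header. Restart-duplicated time blocks (time jumping backward) are
#' deduplicated keeping the later block, with a warning.
#'
#' @param path COLVAR file.
#' @return a data frame with the header's column names, time non-decreasing.
#' @export
read_colvar <- function(path) {
  tab <- read_plumed_table(path)
  if (!"time" %in% names(tab)) stop("COLVAR file lacks a time column")
  dedup_restarts(tab, path)
}

#' Convert a COLVAR table to a trajectory
#'
#' @param tab data frame from [read_colvar()].
#' @param cv_cols CV column names (default: everything except `time`).
#' @return a `cv_trajectory`.
#' @export
colvar_to_trajectory <- function(tab, cv_cols = setdiff(names(tab), "time")) {
  cv_trajectory(tab$time, as.matrix(tab[cv_cols]))
}

#' Read a PLUMED HILLS file
#'
#' Expects columns `time`, one center per CV, one `sigma_*` per CV,
#' `height`, and optionally `biasf`. A `biasf` value > 1 marks the log as
#' well-tempered.
#'
#' @param path HILLS file.
#' @param kT thermal energy to attach to the log.
#' @return a `hills_log`.
#' @export
read_hills <- function(path, kT = 1) {
  tab <- read_plumed_table(path, allow_empty = TRUE)
  if (nrow(tab) == 0L) {
    d <- sum(grepl("^sigma_", names(tab)))
    if (d == 0L) stop("HILLS file needs one sigma_* column per CV column")
    return(empty_hills_log(d, kT = kT))
  }
  if (!"time" %in% names(tab)) stop("HILLS file lacks a time column")
  tab <- dedup_restarts(tab, path)
  sig_cols <- grep("^sigma_", names(tab), value = TRUE)
  cv_cols <- setdiff(names(tab), c("time", "height", "biasf", sig_cols))
  if (!length(sig_cols) || length(sig_cols) != length(cv_cols))
    stop("HILLS file needs one sigma_* column per CV column")
  if (!"height" %in% names(tab)) stop("HILLS file lacks a height column")
  bad <- which(as.matrix(tab[sig_cols]) <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("HILLS line %d: sigma must be positive", bad[1, 1] + 1L))
  gamma <- NULL
  if ("biasf" %in% names(tab)) {
    bf <- tab$biasf[1]
    if (is.finite(bf) && bf > 1) gamma <- bf
  }
  hills_log(time = tab$time, center = as.matrix(tab[cv_cols]),
            sigma = as.matrix(tab[sig_cols]), height = tab$height,
            bias_factor = gamma, kT = kT)
}

read_plumed_table <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- which(startsWith(lines, "#! FIELDS"))
  if (!length(hdr_idx)) stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[hdr_idx[1]])),
                     "\\s+")[[1]]
  if (anyDuplicated(fields)) stop("duplicate column names in FIELDS header")
  set_lines <- grepl("^#! SET", lines)
  unsupported <- grepl("multivariate", lines[set_lines]) &
    !grepl("multivariate false", lines[set_lines])
  if (any(unsupported))
    stop("unsupported dialect: multivariate hills are not handled")
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    if (allow_empty) {
      tab <- as.data.frame(matrix(numeric(0), 0, length(fields)))
      names(tab) <- fields
      return(tab)
    }
    stop("empty data section in ", path)
  }
  rows <- strsplit(trimws(lines[body_idx]), "\\s+")
  widths <- lengths(rows)
  if (any(widths != length(fields)))
    stop(sprintf("parse error at line %d of %s: expected %d columns, got %d",
                 body_idx[which(widths != length(fields))[1]], path,
                 length(fields), widths[widths != length(fields)][1]))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / length(fields))
    stop(sprintf("parse error at line %d of %s: non-numeric cell",
                 body_idx[bad_row], path))
  }
  tab <- as.data.frame(matrix(vals, ncol = length(fields), byrow = TRUE))
  names(tab) <- fields
  tab
}

dedup_restarts <- function(tab, path) {
  t <- tab$time
  drops <- which(diff(t) <= 0)
  while (length(drops)) {
    j <- drops[1] + 1L # first row of the later (restarted) block
    cut <- which(t[seq_len(j - 1L)] >= t[j])
    tab <- tab[-cut, , drop = FALSE]
    warning(sprintf(
      "restart overlap in %s: dropped %d earlier rows, keeping later block",
      path, length(cut)), call. = FALSE)
    t <- tab$time
    drops <- which(diff(t) <= 0)
  }
  rownames(tab) <- NULL
  tab
}

plumed_write_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(tab), collapse = " ")), con)
  if (nrow(tab)) {
    cells <- vapply(tab, function(col) sprintf("%.17g", col),
                    character(nrow(tab)))
    if (!is.matrix(cells)) cells <- matrix(cells, nrow = nrow(tab))
    writeLines(apply(cells, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Write a COLVAR file
#'
#' @param x a `cv_trajectory` or a data frame with a `time` column.
#' @param path output file.
#' @param cv_names CV column names (trajectory input).
#' @export
write_colvar <- function(x, path, cv_names = NULL) {
  if (inherits(x, "cv_trajectory")) {
    d <- ncol(x$samples)
    if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
    tab <- data.frame(time = x$times)
    tab[cv_names] <- as.data.frame(x$samples)
    x <- tab
  }
  plumed_write_table(x, path)
}

#' Write a HILLS file
#'
#' Emits `time`, per-CV centers, `sigma_*`, `height` and (for well-tempered
#' logs) `biasf`, at full double precision so write/read round-trips are
#' bit-faithful.
#'
#' @param log a `hills_log`.
#' @param path output file.
#' @param cv_names CV column names.
#' @export
write_hills <- function(log, path, cv_names = NULL) {
  d <- log$ndim
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  tab <- data.frame(time = log$hills$time)
  tab[cv_names] <- as.data.frame(log$hills$center)
  tab[paste0("sigma_", cv_names)] <- as.data.frame(log$hills$sigma)
  tab$height <- log$hills$height
  if (!is.null(log$bias_factor)) tab$biasf <- log$bias_factor
  plumed_write_table(tab, path)
}

#' Write a simulation's COLVAR and HILLS files
#'
#' @param sim a `sim_output`.
#' @param dir output directory.
#' @param tag file tag; writes `COLVAR.<tag>` and `HILLS.<tag>`.
#' @return character vector of the paths written.
#' @export
write_sim_output <- function(sim, dir, tag = "0") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, paste0("COLVAR.", tag))
  write_colvar(sim$trajectory, cp)
  hp <- file.path(dir, paste0("HILLS.", tag))
  write_hills(sim$hills, hp)
  c(colvar = cp, hills = hp)
}
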