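# Plain-text interchange formats and run configuration.
#
# Pattern files: header "m n M side", then one line per pattern with
# space-separated 0-based active indices (possibly empty). Binary matrices:
# coordinate list with header "i j" pairs, or dense CSV. All indices are
# 0-based on disk.

#' Write one side of a pattern set as plain text
#'
#' @param patterns a \code{pattern_set}.
#' @param path output file.
#' @param side \code{"u"} or \code{"v"}.
#' @export
write_pattern_set <- function(patterns, path, side = c("u", "v")) {
  side <- match.arg(side)
  len <- if (side == "u") patterns$m else patterns$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(len, if (side == "u") patterns$n else patterns$m,
                   patterns$M, side), con)
  for (mu in seq_len(patterns$M))
    writeLines(paste(patterns[[side]][[mu]], collapse = " "), con)
  invisible(path)
}

#' Read a pattern file written by \code{\link{write_pattern_set}}
#'
#' @param path file path.
#' @return List with \code{size}, \code{M}, \code{side}, and the 0-based
#'   index lists \code{patterns}.
#' @export
read_pattern_set <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  size <- as.integer(hdr[1]); M <- as.integer(hdr[3]); side <- hdr[4]
  pats <- lapply(seq_len(M), function(i) {
    ln <- trimws(lines[i + 1L])
    if (!nzchar(ln)) return(integer(0))
    idx <- as.integer(strsplit(ln, "\\s+")[[1]])
    if (any(idx < 0 | idx >= size)) stop("index out of range in ", path)
    sort(idx)
  })
  list(size = size, M = M, side = side, patterns = pats)
}

#' Write a binary matrix as a coordinate list or dense CSV
#'
#' Coordinate format: header line \code{"coo m n"}, then one \code{"i j"}
#' line per nonzero entry (0-based).
#'
#' @param x matrix.
#' @param path output file.
#' @param format \code{"coo"} or \code{"csv"}.
#' @export
write_binary_matrix <- function(x, path, format = c("coo", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(x, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    nz <- which(x != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("coo", nrow(x), ncol(x)), con)
    if (nrow(nz))
      writeLines(paste(nz[, 1] - 1L, nz[, 2] - 1L), con)
    invisible(path)
  }
}

#' Read a binary matrix written by \code{\link{write_binary_matrix}}
#'
#' @param path file path; the format is detected from the first line.
#' @export
read_binary_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "coo")) {
    hdr <- strsplit(trimws(first), "\\s+")[[1]]
    m <- as.integer(hdr[2]); n <- as.integer(hdr[3])
    out <- matrix(0L, m, n)
    body <- readLines(path)[-1L]
    if (length(body)) {
      ij <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
      out[cbind(ij[, 1] + 1L, ij[, 2] + 1L)] <- 1L
    }
    out
  } else {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  }
}

.config_defaults <- list(
  engine = "macro", model = "A", seed = 1L,
  network = list(m = 1000L, n = 1000L, k = 50L, l = 50L, M = 20L,
                 P = 0.1, P_pot = 1, P1_init = 0),
  plasticity = list(p_c = c(0, 1), p_e = c(0.01, 0), p_d = c(0, 0),
                    p_g = "homeostatic"),
  schedule = list(c(0L, 4L)), t_end = 100L)

#' Parse a YAML run configuration
#'
#' Unknown top-level keys are rejected; missing keys are filled with
#' defaults, and the fully resolved configuration is returned so output
#' metadata can echo it.
#'
#' @param path YAML file.
#' @return Named list (the resolved configuration).
#' @export
parse_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(.config_defaults, cfg)
  for (nm in c("p_c", "p_e", "p_d")) {
    v <- out$plasticity[[nm]]
    if (any(v < 0 | v > 1))
      stop("configuration key plasticity$", nm, " must lie in [0, 1]")
  }
  out
}

#' Write a configuration to YAML
#' @param cfg configuration list.
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Named fixture presets
#'
#' Canonical simulation setups:
#' \describe{
#'   \item{fig9a}{spaced rehearsal of M = 20 assemblies of size 50 in a
#'     1000 x 1000 net, P = 0.1, full potential connectivity, turnover
#'     p_e|0 = 0.01, rehearsal in steps 0-4, 100-104, 200-204, 300-304.}
#'   \item{fig11}{two-session protocol net: P = 0.1, P_pot = 0.4, P_1S = 0.1,
#'     p_e|0 = 0.1, p_d|0 = 0.005; rehearse steps 0-9 and step 30.}
#'   \item{fig12-a .. fig12-f}{long-interval spacing parameter sets,
#'     p_e|0 in {0.1, 0.01, 0.001} x p_d|0 in {1e-4, 1e-3}.}
#'   \item{macrocolumn}{cortical macrocolumn constants: n = 1e5, P = 0.1,
#'     P_pot = 0.5 (filling fraction 0.2).}
#' }
#'
#' @param preset preset name.
#' @return Resolved configuration list.
#' @export
fixture_preset <- function(preset) {
  # shallow assignment: presets replace whole top-level blocks
  with_cfg <- function(changes) {
    cfg <- .config_defaults
    cfg[names(changes)] <- changes
    cfg
  }
  fig12 <- function(pe, pd)
    with_cfg(list(
      model = "B",
      network = list(m = NA, n = NA, k = NA, l = NA, M = NA,
                     P = 0.1, P_pot = 0.4, P1_init = 0.02, P_1S = 0.001),
      plasticity = list(p_c = c(0, 1), p_e = c(pe, 0), p_d = c(pd, 0),
                        p_g = "homeostatic"),
      schedule = list(c(0L, 9L)), t_end = NA))
  switch(preset,
    fig9a = with_cfg(list(
      schedule = list(c(0L, 4L), c(100L, 104L), c(200L, 204L),
                      c(300L, 304L)),
      t_end = 404L)),
    fig11 = with_cfg(list(
      model = "B",
      network = list(m = NA, n = NA, k = NA, l = NA, M = NA, P = 0.1,
                     P_pot = 0.4, P1_init = 0, P_1S = 0.1),
      plasticity = list(p_c = c(0, 1), p_e = c(0.1, 0), p_d = c(0.005, 0),
                        p_g = "homeostatic"),
      schedule = list(c(0L, 9L), c(30L, 30L)), t_end = 90L)),
    `fig12-a` = fig12(0.1, 1e-4), `fig12-b` = fig12(0.01, 1e-4),
    `fig12-c` = fig12(0.001, 1e-4), `fig12-d` = fig12(0.1, 1e-3),
    `fig12-e` = fig12(0.01, 1e-3), `fig12-f` = fig12(0.001, 1e-3),
    macrocolumn = with_cfg(list(
      network = list(m = 100000L, n = 100000L, k = 50L, l = 50L, M = NA,
                     P = 0.1, P_pot = 0.5, P1_init = NA))),
    stop("unknown preset: ", preset))
}

#' Generate fixture files
#'
#' Writes pattern sets, masks, or consolidation signals in the package's
#' plain-text formats, or a preset configuration as YAML. The same seed
#' yields byte-identical files.
#'
#' @param kind \code{"patterns"}, \code{"mask"}, \code{"signal"} or
#'   \code{"protocol"}.
#' @param out output file path (patterns get \code{_u}/\code{_v} suffixes).
#' @param m,n,k,l,M,P pattern/mask parameters (as applicable).
#' @param preset preset name for \code{kind = "protocol"}.
#' @param seed integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixture <- function(kind = c("patterns", "mask", "signal", "protocol"),
                         out, m = 100, n = m, k = 10, l = k, M = 10,
                         P = 0.5, preset = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "protocol") {
    if (is.null(preset)) stop("kind = 'protocol' needs a preset name")
    write_config(fixture_preset(preset), out)
    return(invisible(out))
  }
  set.seed(seed)
  if (kind == "patterns") {
    ps <- generate_patterns(m, n, k, l, M, mode = "fixed")
    pu <- sub("(\\.[^.]*)?$", "_u\\1", out)
    pv <- sub("(\\.[^.]*)?$", "_v\\1", out)
    write_pattern_set(ps, pu, "u")
    write_pattern_set(ps, pv, "v")
    return(invisible(c(pu, pv)))
  }
  if (kind == "mask") {
    msk <- matrix(as.integer(runif(m * n) < P), m, n)
    write_binary_matrix(msk, out)
    return(invisible(out))
  }
  ps <- generate_patterns(m, n, k, l, M, mode = "fixed")
  write_binary_matrix(consolidation_signal(ps), out)
  invisible(out)
}
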