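#' @include AllClasses.R surfaces.R cv.R string.R
NULL

.fullPrecision <- function(x) sprintf("%.17g", x)

# header lines common to every text artifact: version, master seed, config
# hash, and a hash of the data section (timestamp-free, diff-able)
.archiveHeader <- function(masterSeed, configHash, dataLines) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(dataLines, tmp)
  c(sprintf("# mfepath_version=%s", as.character(packageVersion("MFEPath"))),
    sprintf("# master_seed=%d", as.integer(masterSeed)),
    sprintf("# config_hash=%s", configHash),
    sprintf("# content_md5=%s", unname(md5sum(tmp))))
}

.hashList <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(md5sum(tmp))
}

#' Write per-cycle string paths to a delimited text archive
#'
#' One row per (cycle, image): cycle, image, alpha, then one column per CV
#' in declaration order, at full decimal precision so that reading the
#' archive back reproduces the values bit for bit.
#'
#' @param paths list of \code{\linkS4class{StringPath}} objects (or one).
#' @param dest output file path.
#' @param cvLabels CV column names.
#' @param masterSeed seed recorded in the header.
#' @param configHash configuration hash recorded in the header.
#' @return \code{dest}, invisibly.
#' @export
writePathArchive <- function(paths, dest, cvLabels = NULL, masterSeed = 0L,
                             configHash = "unset") {
  if (is(paths, "StringPath")) paths <- list(paths)
  if (!length(paths)) stop("no paths to write")
  N <- ncol(paths[[1]]@images)
  if (is.null(cvLabels)) cvLabels <- sprintf("cv_%d", seq_len(N))
  rows <- unlist(lapply(paths, function(p) {
    vapply(seq_len(nrow(p@images)), function(r)
      paste(c(p@cycle, r, .fullPrecision(c(p@alphas[r], p@images[r, ]))),
            collapse = "\t"), character(1))
  }))
  header <- paste(c("cycle", "image", "alpha", cvLabels), collapse = "\t")
  lines <- c(header, rows)
  writeLines(c(.archiveHeader(masterSeed, configHash, lines), lines), dest)
  invisible(dest)
}

#' Read a string path archive
#'
#' @param src file written by \code{\link{writePathArchive}}.
#' @return list with \code{paths} (list of \code{\linkS4class{StringPath}}),
#'   \code{cvLabels} and \code{header} metadata.
#' @export
readPathArchive <- function(src) {
  lines <- readLines(src)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  cols <- strsplit(body[1], "\t")[[1]]
  dat <- read.table(text = body[-1], sep = "\t", col.names = cols,
                    colClasses = "numeric")
  cvLabels <- cols[-(1:3)]
  paths <- lapply(split(dat, dat$cycle), function(dd) {
    dd <- dd[order(dd$image), ]
    stringPath(as.matrix(dd[, cvLabels, drop = FALSE]), dd$alpha,
               cycle = dd$cycle[1])
  })
  names(paths) <- NULL
  list(paths = paths, cvLabels = cvLabels, header = meta)
}

#' Write a free-energy profile as delimited text
#'
#' Columns: alpha, G, stderr; full precision; standard artifact header.
#'
#' @param profile a \code{\linkS4class{FreeEnergyProfile}}.
#' @inheritParams writePathArchive
#' @return \code{dest}, invisibly.
#' @export
writeProfileTable <- function(profile, dest, masterSeed = 0L,
                              configHash = "unset") {
  rows <- vapply(seq_along(profile@alphaGrid), function(i)
    paste(.fullPrecision(c(profile@alphaGrid[i], profile@G[i],
                           profile@stderr[i])), collapse = "\t"),
    character(1))
  lines <- c("alpha\tG\tstderr", rows)
  writeLines(c(.archiveHeader(masterSeed, configHash, lines), lines), dest)
  invisible(dest)
}

#' Write a stationary-state table as delimited text
#'
#' Mirrors the usual layout of MFEP stationary-state tables: label, alpha,
#' free energy, then one column per CV.
#'
#' @param states data.frame from \code{\link{locateStationaryStates}}.
#' @inheritParams writePathArchive
#' @return \code{dest}, invisibly.
#' @export
writeStationaryTable <- function(states, dest, masterSeed = 0L,
                                 configHash = "unset") {
  num <- vapply(states, is.numeric, logical(1))
  body <- states
  body[num] <- lapply(states[num], .fullPrecision)
  rows <- apply(body, 1, paste, collapse = "\t")
  lines <- c(paste(names(states), collapse = "\t"), rows)
  writeLines(c(.archiveHeader(masterSeed, configHash, lines), lines), dest)
  invisible(dest)
}

#' Write configurations as multi-frame XYZ
#'
#' Standard XYZ: atom-count line, comment line carrying the frame label,
#' one atom per line.  Two-dimensional configurations are written as a
#' single pseudo-atom padded with z = 0 (flagged in the comment);
#' otherwise the dimension must be divisible by 3.
#'
#' @param configs matrix of configurations (one per row) or list.
#' @param labels per-frame comment labels.
#' @param dest output file path.
#' @param element element symbol(s) for the atom lines.
#' @return \code{dest}, invisibly.
#' @export
writeXYZSnapshots <- function(configs, labels = NULL, dest, element = "X") {
  if (is.list(configs)) configs <- do.call(rbind, configs)
  configs <- as.matrix(configs)
  if (!nrow(configs)) {
    warning("no configurations: writing an empty XYZ file")
    writeLines(character(0), dest)
    return(invisible(dest))
  }
  d <- ncol(configs)
  padded <- FALSE
  if (d == 2L) {
    configs <- cbind(configs, 0)
    d <- 3L; padded <- TRUE
  }
  if (d %% 3L != 0L)
    stop("configuration dimension must be divisible by 3 (or be 2-D)")
  nat <- d %/% 3L
  el <- rep_len(element, nat)
  if (is.null(labels)) labels <- sprintf("frame %d", seq_len(nrow(configs)))
  con <- file(dest, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(configs))) {
    writeLines(as.character(nat), con)
    writeLines(paste0(labels[i],
                      if (padded) " (2-D configuration padded to z=0)"), con)
    xyz <- matrix(configs[i, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%s %.10f %.10f %.10f", el,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(dest)
}
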