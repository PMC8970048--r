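# Volume I/O: MRC2014 binary volumes (mode 2 float32 canonical on disk;
# modes 0/1/6 converted on read) and a native .rds array dialect, plus CSV
# dataset manifests (columns path,domain,label).

MRC_HEADER_BYTES <- 1024L

#' Read a cubic volume from disk
#'
#' Reads an MRC2014 file (\code{.mrc}, \code{.map}, \code{.rec}) or a native
#' R array file (\code{.rds}). Non-cubic grids are rejected. Voxel spacing is
#' taken from the MRC cell dimensions (Angstrom in the header, reported in nm)
#' when present.
#'
#' @param path file to read.
#' @return A \linkS4class{TomoVolume}.
#' @seealso \code{\link{writeVolume}}, \code{\link{normalizeVolume}}
#' @examples
#' p <- tempfile(fileext = ".mrc")
#' writeVolume(TomoVolume(array(rnorm(8^3), c(8, 8, 8))), p)
#' readVolume(p)
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    a <- readRDS(path)
    if (!is.array(a) || length(dim(a)) != 3L) stop("rds file does not hold a rank-3 array: ", path)
    checkCubic(dim(a), path)
    sp <- attr(a, "voxelSpacing")
    return(TomoVolume(array(as.numeric(a), dim(a)),
                      voxelSpacing = if (is.null(sp)) 1.0 else sp,
                      provenance = path))
  }
  readMrc(path)
}

readMrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr) < MRC_HEADER_BYTES) stop("unreadable MRC header (file too short): ", path)
  int_at <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "integer", 1, 4, endian = "little")
  num_at <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "numeric", 1, 4, endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  xlen <- num_at(11)
  nsymbt <- int_at(24)
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 4096))
    stop("unreadable MRC header (implausible dimensions): ", path)
  checkCubic(c(nx, ny, nz), path)
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  nvox <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", mode, " in ", path))
  if (length(data) < nvox) stop("truncated MRC data block: ", path)
  spacing <- if (mx > 0 && xlen > 0) xlen / mx / 10 else 1.0  # Angstrom -> nm
  TomoVolume(array(data, c(nx, ny, nz)), voxelSpacing = spacing, provenance = path)
}

checkCubic <- function(d, path) {
  if (length(unique(d)) != 1L) {
    stop(sprintf("non-cubic grid %s in %s; cubic volumes required",
                 paste(d, collapse = " x "), path))
  }
  invisible(TRUE)
}

#' Write a volume to disk
#'
#' MRC2014 mode 2 (32-bit float, little endian) for \code{.mrc}/\code{.map}/
#' \code{.rec} paths, native \code{.rds} otherwise. Voxel spacing is recorded
#' in the MRC cell fields (nm converted to Angstrom).
#'
#' @param volume a \linkS4class{TomoVolume}.
#' @param path destination file; its directory must exist.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "TomoVolume"))
  validObject(volume)
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    a <- volume@data
    attr(a, "voxelSpacing") <- volume@voxelSpacing
    saveRDS(a, path)
    return(invisible(path))
  }
  n <- dim(volume@data)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(n)                       # nx ny nz
  wint(2L)                      # mode 2: float32
  wint(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wint(n)                       # mx my mz
  wflt(n * volumeSpacingA(volume))  # cella (Angstrom)
  wflt(c(90, 90, 90))           # cellb
  wint(c(1L, 2L, 3L))           # mapc mapr maps
  wflt(c(min(volume@data), max(volume@data), mean(volume@data)))  # dmin dmax dmean
  wint(0L)                      # ispg
  wint(0L)                      # nsymbt
  writeBin(raw(100), con)       # extra
  wflt(c(0, 0, 0))              # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wflt(sd(as.numeric(volume@data)))                 # rms
  wint(0L)                      # nlabl
  writeBin(raw(800), con)       # labels
  wflt(as.numeric(volume@data))
  invisible(path)
}

volumeSpacingA <- function(volume) volume@voxelSpacing * 10

#' Normalize a volume to the generator range [-1, 1]
#'
#' \code{minmax_sym} maps the minimum to -1 and the maximum to +1 linearly;
#' \code{zscore_clip} standardizes to zero mean/unit variance, clips to
#' [-3, 3] and rescales to [-1, 1]. A constant volume maps to all zeros in
#' either mode so that degenerate inputs never abort a pipeline.
#'
#' @param volume a \linkS4class{TomoVolume} (finite values).
#' @param mode \code{"minmax_sym"} (default) or \code{"zscore_clip"}.
#' @return A normalized \linkS4class{TomoVolume} with values in [-1, 1].
#' @export
normalizeVolume <- function(volume, mode = c("minmax_sym", "zscore_clip")) {
  mode <- match.arg(mode)
  x <- volume@data
  rng <- range(x)
  if (rng[1] == rng[2]) {
    y <- array(0, dim(x))
  } else if (mode == "minmax_sym") {
    y <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
  } else {
    z <- (x - mean(x)) / sd(as.numeric(x))
    y <- pmin(pmax(z, -3), 3) / 3
  }
  TomoVolume(y, voxelSpacing = volume@voxelSpacing,
             provenance = paste0(volume@provenance,
                                 if (nzchar(volume@provenance)) "|" else "",
                                 "norm:", mode))
}

#' Write a dataset manifest and its volumes
#'
#' Writes each volume as MRC under \code{dir} and a CSV manifest with columns
#' \code{path,domain,label} (label empty for unlabeled rows).
#'
#' @param dataset a \linkS4class{DomainDataset}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the volumes.
#' @return Path of the manifest CSV.
#' @export
writeDataset <- function(dataset, dir, prefix = tolower(domainTag(dataset))) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nvol <- length(dataset@volumes)
  paths <- file.path(dir, sprintf("%s_%04d.mrc", prefix, seq_len(nvol)))
  for (i in seq_len(nvol)) writeVolume(dataset@volumes[[i]], paths[i])
  labels <- if (length(dataset@labels)) dataset@labels else rep("", nvol)
  manifest <- data.frame(path = basename(paths), domain = dataset@domain,
                         label = labels, stringsAsFactors = FALSE)
  mpath <- file.path(dir, paste0(prefix, "_manifest.csv"))
  write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Read a dataset from a CSV manifest
#'
#' The manifest must have columns \code{path,domain,label}; relative paths are
#' resolved against the manifest's directory. Empty labels mark unlabeled
#' rows; the dataset is labeled only if every row carries a label.
#'
#' @param manifestPath path to the manifest CSV.
#' @param domain optional domain filter ("S" or "D"); default reads all rows
#'   and requires them to share one domain tag.
#' @return A \linkS4class{DomainDataset}.
#' @export
readDataset <- function(manifestPath, domain = NULL) {
  if (!file.exists(manifestPath)) stop("no such manifest: ", manifestPath)
  m <- read.csv(manifestPath, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("path", "domain", "label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns path,domain,label; got: ",
         paste(names(m), collapse = ","))
  }
  if (!is.null(domain)) m <- m[m$domain == domain, , drop = FALSE]
  if (nrow(m) == 0) stop("manifest has no rows", if (!is.null(domain)) paste0(" for domain ", domain))
  dom <- unique(m$domain)
  if (length(dom) != 1L) stop("manifest mixes domains ", paste(dom, collapse = ","),
                              "; pass domain= to select one")
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                  file.path(dirname(manifestPath), m$path))
  vols <- lapply(paths, readVolume)
  labels <- if (all(nzchar(m$label))) m$label else character(0)
  DomainDataset(vols, domain = dom, labels = labels, manifestPath = manifestPath)
}
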