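#' Read a long-format voxel table
#'
#' Reads a TSV with columns \code{probe_id, x, y, z} and either
#' \code{energy} or the pair \code{intensity, density} (converted on load
#' via \code{\link{expressionEnergy}}), and assembles a
#' \linkS4class{VoxelExperiment} on the supplied ontology's lattice.
#' Missing voxels default to 0 energy.
#'
#' @param path TSV file path.
#' @param ont a \linkS4class{RegionOntology}.
#' @return a \linkS4class{VoxelExperiment}.
#' @export
readVoxelTable <- function(path, ont) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  shape <- dim(ont@labels)
  if (!all(c("probe_id", "x", "y", "z") %in% names(df)))
    stop("voxel table needs probe_id, x, y, z columns")
  if (!"energy" %in% names(df)) {
    if (!all(c("intensity", "density") %in% names(df)))
      stop("voxel table needs energy or intensity+density columns")
    df$energy <- expressionEnergy(df$intensity, df$density)
  }
  if (any(df$x < 1 | df$x > shape[1] | df$y < 1 | df$y > shape[2] |
          df$z < 1 | df$z > shape[3]))
    stop("voxel coordinates outside the lattice")
  ids <- unique(df$probe_id)
  e <- matrix(0, length(ids), prod(shape), dimnames = list(ids, NULL))
  vox <- (df$z - 1L) * shape[1] * shape[2] + (df$y - 1L) * shape[1] + df$x
  e[cbind(match(df$probe_id, ids), vox)] <- df$energy
  VoxelExperiment(e, ont)
}

#' Write a VoxelExperiment as a long-format voxel table
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param path output TSV path.
#' @param dropZero omit zero-energy voxels (default TRUE).
#' @export
writeVoxelTable <- function(x, path, dropZero = TRUE) {
  e <- energyMatrix(x)
  cd <- colData(x)
  ids <- rownames(e)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(e)))
  df <- data.frame(probe_id = rep(ids, each = ncol(e)),
                   x = rep(cd$x, nrow(e)), y = rep(cd$y, nrow(e)),
                   z = rep(cd$z, nrow(e)),
                   energy = as.vector(t(e)))
  if (dropZero) df <- df[df$energy > 0, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a region ontology as JSON
#'
#' The JSON carries the lattice shape, the coarse-of mapping, region names
#' and the flattened voxel label array.
#'
#' @param ont a \linkS4class{RegionOntology}.
#' @param path JSON file path.
#' @export
writeOntology <- function(ont, path) {
  obj <- list(lattice_shape = dim(ont@labels),
              coarse_of = ont@coarseOf,
              fine_names = ont@fineNames,
              coarse_names = ont@coarseNames,
              labels = as.integer(ont@labels))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeOntology
#' @export
readOntology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  RegionOntology(array(as.integer(obj$labels), dim = obj$lattice_shape),
                 as.integer(obj$coarse_of),
                 fineNames = obj$fine_names,
                 coarseNames = obj$coarse_names)
}

#' Read JASPAR-style PWM text
#'
#' Parses records of the form \preformatted{>MA0001 name
#' A [ 1 2 3 ]
#' C [ 0 1 0 ]
#' G [ 2 0 1 ]
#' T [ 1 3 0 ]}
#' (brackets optional; T rows are read as U). Counts are normalised to
#' column probabilities.
#'
#' @param path text file path.
#' @return list of \linkS4class{PWMotif} objects.
#' @export
readPwmJaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' record headers found")
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body, function(l) {
      base <- sub("^\\s*([ACGTUacgtu]).*", "\\1", l)
      rest <- sub("^\\s*[ACGTUacgtu]", "", l)
      nums <- regmatches(rest, gregexpr("[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?",
                                        rest))[[1]]
      list(base = toupper(base), vals = as.numeric(nums))
    })
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- vapply(rows, `[[`, character(1), "base")
    pwMotif(id, m)
  })
}

#' Export gene parts, probes or structures as BED
#'
#' Thin wrapper over \code{rtracklayer::export} (0-based half-open on
#' disk, converted from the in-memory 1-based GRanges); the BED name field
#' carries the first metadata column.
#'
#' @param gr a GRanges.
#' @param path output .bed path.
#' @export
writeBed <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED export")
  if (ncol(mcols(gr)) > 0) {
    names(gr) <- as.character(mcols(gr)[[1]])
    mcols(gr) <- NULL
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeBed
#' @param nameCol metadata column name to store the BED name field in.
#' @export
readBed <- function(path, nameCol = "name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED import")
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(mcols(gr))[names(mcols(gr)) == "name"] <- nameCol
  gr
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of RNA sequences.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(chartr("T", "U", toupper(seqs))), path)
  invisible(path)
}

#' @rdname writeFasta
#' @export
readFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(chartr("Tt", "Uu", toupper(as.character(x))), names(x))
}
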