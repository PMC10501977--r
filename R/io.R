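## File formats.
##
## Keypoint files: JSON (one object per image: image_id, view, and a list of
## {label, x, y, visible}) and CSV (long format: image_id, view, label, x,
## y, visible).  Coordinates are 0-based pixel centers, x = column,
## y = row.  QC reports: CSV and JSON, one record per image.

#' Write keypoint sets to JSON
#'
#' @param kpsList list of \code{\link{KeypointSet}} objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeKeypointsJSON <- function(kpsList, path) {
    if (methods::is(kpsList, "KeypointSet")) kpsList <- list(kpsList)
    recs <- lapply(kpsList, function(k) {
        pts <- lapply(which(k@visible | rowSums(is.finite(k@coords)) == 2L),
                      function(i) list(label = KP_LABELS[i],
                                       x = k@coords[i, "x"],
                                       y = k@coords[i, "y"],
                                       visible = unname(k@visible[i])))
        list(image_id = k@imageId, view = k@view,
             keypoints = unname(pts))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read keypoint sets from JSON
#'
#' @param path a JSON file written in the dialect of
#'   \code{\link{writeKeypointsJSON}}.
#' @return list of \code{\link{KeypointSet}} objects.
#' @export
readKeypointsJSON <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(recs, function(r) {
        labs <- vapply(r$keypoints, function(p) p$label, character(1))
        coords <- cbind(x = vapply(r$keypoints, function(p)
                            as.numeric(p$x), numeric(1)),
                        y = vapply(r$keypoints, function(p)
                            as.numeric(p$y), numeric(1)))
        rownames(coords) <- labs
        vis <- stats::setNames(vapply(r$keypoints, function(p)
            isTRUE(p$visible), logical(1)), labs)
        keypointSet(coords, view = r$view, visible = vis,
                    imageId = r$image_id)
    })
}

#' Write keypoint sets to long-format CSV
#'
#' @inheritParams writeKeypointsJSON
#' @export
writeKeypointsCSV <- function(kpsList, path) {
    if (methods::is(kpsList, "KeypointSet")) kpsList <- list(kpsList)
    rows <- do.call(rbind, lapply(kpsList, function(k) {
        keep <- k@visible | rowSums(is.finite(k@coords)) == 2L
        data.frame(image_id = k@imageId, view = k@view,
                   label = KP_LABELS[keep],
                   x = k@coords[keep, "x"], y = k@coords[keep, "y"],
                   visible = k@visible[keep])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
    invisible(path)
}

#' Read keypoint sets from long-format CSV
#'
#' @param path a CSV with columns image_id, view, label, x, y, visible.
#' @return list of \code{\link{KeypointSet}} objects.
#' @export
readKeypointsCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("image_id", "view", "label", "x", "y", "visible")
    if (!all(need %in% names(df)))
        stop("keypoint CSV must have columns: ", paste(need, collapse = ", "))
    lapply(split(df, factor(df$image_id, levels = unique(df$image_id))),
           function(d) {
        coords <- cbind(x = d$x, y = d$y)
        rownames(coords) <- d$label
        keypointSet(coords, view = d$view[1],
                    visible = stats::setNames(as.logical(d$visible),
                                              d$label),
                    imageId = d$image_id[1])
    })
}

## ---- 16-bit grayscale PNG -------------------------------------------------

.crc32Table <- local({
    tab <- NULL
    function() {
        if (!is.null(tab)) return(tab)
        t <- integer(256)
        for (n in 0:255) {
            c <- n
            for (k in 1:8)
                c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(
                    bitwAnd(c, -2L), 1)) else bitwShiftR(bitwAnd(c, -2L), 1)
            t[n + 1] <- c
        }
        tab <<- t
        tab
    }
})

.crc32 <- function(bytes) {
    tab <- .crc32Table()
    crc <- -1L
    for (b in as.integer(bytes)) {
        idx <- bitwAnd(bitwXor(crc, b), 255L) + 1L
        crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx])
    }
    bitwXor(crc, -1L)
}

.u32be <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

.pngChunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(.u32be(length(data)), body, .u32be(.crc32(body)))
}

#' Write a 16-bit grayscale PNG
#'
#' Intensities in [0, 1] are quantized to 16 bits.  The file reads back
#' bit-exactly with \code{png::readPNG}.
#'
#' @param image numeric matrix (rows x cols) with values in [0, 1].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePNG16 <- function(image, path) {
    stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 1)
    H <- nrow(image); W <- ncol(image)
    v <- as.integer(round(t(image) * 65535))     # row-major scan order
    dim(v) <- NULL
    pix <- writeBin(v, raw(), size = 2L, endian = "big")
    dim(pix) <- c(2L * W, H)
    scan <- as.vector(rbind(as.raw(0L), pix))    # filter byte 0 per row
    ihdr <- c(.u32be(W), .u32be(H),
              as.raw(c(16L, 0L, 0L, 0L, 0L)))   # 16-bit, grayscale
    out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             .pngChunk("IHDR", ihdr),
             .pngChunk("IDAT", memCompress(scan, "gzip")),
             .pngChunk("IEND", raw(0)))
    writeBin(out, path)
    invisible(path)
}

## ---- NPY export -----------------------------------------------------------

#' Write a heatmap stack as an NPY array
#'
#' Writes the h x w x 9 array in NPY format (version 1.0, float64,
#' Fortran order) so heatmaps can be inspected with standard array tools.
#'
#' @param stack a \code{\link{HeatmapStack}} (or a numeric array).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHeatmapsNPY <- function(stack, path) {
    a <- if (methods::is(stack, "HeatmapStack")) stack@maps else stack
    stopifnot(is.array(a), is.numeric(a))
    hdr <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%s), }",
                   paste(dim(a), collapse = ", "))
    ## pad with spaces so that magic+header is a multiple of 64, \n-final
    pad <- 64L - ((10L + nchar(hdr) + 1L) %% 64L)
    hdr <- paste0(hdr, strrep(" ", pad), "\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
    writeBin(writeBin(nchar(hdr), raw(), size = 2L,
                      endian = "little"), con)
    writeBin(charToRaw(hdr), con)
    writeBin(as.vector(a), con, size = 8L, endian = "little")
    invisible(path)
}

## ---- QC reports -----------------------------------------------------------

#' Write a QC report
#'
#' The CSV holds the per-image records; the JSON wraps them together with
#' the run's provenance (package version, decoding settings, model
#' checksum) so a report can be traced back to the configuration that
#' produced it.
#'
#' @param records data.frame as produced by \code{\link{runQC}}.
#' @param csvPath,jsonPath output files (either may be \code{NULL}).
#' @param provenance optional named list recorded in the JSON report.
#' @return the records, invisibly.
#' @export
writeQCReport <- function(records, csvPath = NULL, jsonPath = NULL,
                          provenance = NULL) {
    if (!is.null(csvPath))
        utils::write.csv(records, csvPath, row.names = FALSE)
    if (!is.null(jsonPath)) {
        payload <- if (is.null(provenance)) records
                   else list(provenance = provenance, records = records)
        jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                             digits = NA, na = "null", dataframe = "rows")
    }
    invisible(records)
}
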