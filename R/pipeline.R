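## End-to-end orchestration: preprocessing, detection, geometry, reporting.

#' Preprocess a radiograph for detection
#'
#' Reads an 8- or 16-bit grayscale PNG (or accepts a numeric matrix),
#' applies contrast-limited adaptive histogram equalization (CLAHE) and
#' rescales to [0, 1].  Constant (no-contrast) images are passed through
#' unchanged.  DICOM input is not supported; convert to 16-bit PNG
#' beforehand.
#'
#' @param input path to a PNG file, or a numeric matrix (rows x cols).
#' @param clahe logical; apply CLAHE (default \code{TRUE}).
#' @param tiles number of contextual tiles per dimension (default 8).
#' @param clipLimit CLAHE contrast limit (EBImage convention; default 2).
#' @return numeric matrix with values in [0, 1].
#' @export
preprocess <- function(input, clahe = TRUE, tiles = 8L, clipLimit = 2) {
    if (is.character(input)) {
        if (!file.exists(input)) stop("unreadable file: ", input)
        img <- png::readPNG(input)
        if (length(dim(img)) == 3L) {
            if (dim(img)[3] > 2L)
                stop("color images are not supported; expected grayscale")
            img <- img[, , 1L]        # gray + alpha: keep gray
        }
    } else if (is.matrix(input) && is.numeric(input)) {
        img <- input
    } else stop("input must be a PNG path or a numeric grayscale matrix")
    if (!all(is.finite(img))) stop("non-finite pixel values")
    rng <- range(img)
    if (diff(rng) <= 0) return(matrix(0.5, nrow(img), ncol(img)))
    img <- (img - rng[1]) / diff(rng)
    if (clahe) {
        eq <- EBImage::clahe(EBImage::Image(t(img)), nx = tiles, ny = tiles,
                             limit = clipLimit)
        img <- t(EBImage::imageData(eq))
        rng <- range(img)
        if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    }
    pmin(pmax(img, 0), 1)
}

.qcRecord <- function(id) {
    data.frame(image_id = id, view_call = NA_character_,
               overlap_ratio = NA_real_, flexion_angle_deg = NA_real_,
               normalized_flexion = NA_real_, mean_score = NA_real_,
               flags = "", stringsAsFactors = FALSE)
}

#' Run the QC pipeline over a batch
#'
#' For image inputs: preprocess, predict heatmaps, decode keypoints,
#' identify the view, compute the QC criteria.  Keypoint-file inputs bypass
#' detection and go straight to the geometric calculation, which makes the
#' two paths interchangeable when the detector returns the annotated
#' keypoints.  Per-image failures are recorded in the report rather than
#' aborting the batch.
#'
#' @param images character vector of PNG paths, or a list of numeric
#'   matrices (optionally named by image id); requires \code{model}.
#' @param keypoints list of \code{\link{KeypointSet}} objects, or the path
#'   of a keypoint JSON/CSV file; bypasses detection.
#' @param model a trained \code{\link{KneeNet}} (needed for images).
#' @param tau detection threshold (default 0.1).
#' @param refine sub-pixel decoding (default \code{TRUE} for the image
#'   path, where argmax quantization at stride 4 would dominate the error).
#' @param clahe apply CLAHE preprocessing to images (default \code{TRUE}).
#' @param csvPath,jsonPath optional report outputs.
#' @return data.frame with one row per input: image id, view call, the QC
#'   criteria, the mean detection score and a semicolon-separated flag list
#'   (\code{clamped_ratio}, \code{low_confidence}, \code{degenerate_geometry}).
#' @export
runQC <- function(images = NULL, keypoints = NULL, model = NULL,
                  tau = 0.1, refine = TRUE, clahe = TRUE,
                  csvPath = NULL, jsonPath = NULL) {
    recs <- list()
    if (!is.null(keypoints)) {
        if (is.character(keypoints))
            keypoints <- if (grepl("\\.json$", keypoints, ignore.case = TRUE))
                readKeypointsJSON(keypoints) else readKeypointsCSV(keypoints)
        for (k in keypoints)
            recs[[length(recs) + 1L]] <- .qcFromKeypoints(k@imageId, k, NULL)
    }
    if (!is.null(images) && length(images)) {
        if (is.null(model))
            stop("image inputs require a trained model")
        if (is.character(images)) {
            ids <- sub("\\.png$", "", basename(images), ignore.case = TRUE)
            imgs <- as.list(images)
        } else {
            imgs <- images
            ids <- if (!is.null(names(images))) names(images)
                   else sprintf("image_%03d", seq_along(images))
        }
        for (i in seq_along(imgs)) {
            rec <- tryCatch({
                arr <- preprocess(imgs[[i]], clahe = clahe)
                dec <- decodeHeatmaps(predictHeatmaps(model, arr),
                                      tau = tau, refine = refine,
                                      imageId = ids[i])
                .qcFromKeypoints(ids[i], NULL, dec)
            }, error = function(e) {
                r <- .qcRecord(ids[i])
                r$flags <- paste0("error:", conditionMessage(e))
                r
            })
            recs[[length(recs) + 1L]] <- rec
        }
    }
    out <- if (length(recs)) do.call(rbind, recs) else .qcRecord("x")[0, ]
    prov <- list(package = as.character(utils::packageVersion("kneeqc")),
                 tau = tau, refine = refine, clahe = clahe,
                 model_checksum = if (is.null(model)) NA else
                     modelChecksum(model))
    writeQCReport(out, csvPath, jsonPath, provenance = prov)
    attr(out, "provenance") <- prov
    out
}

#' Checksum of a detector's parameters
#'
#' A cheap deterministic digest of all weights and biases, recorded in QC
#' report provenance so results can be tied to a specific checkpoint.
#'
#' @param model a \code{\link{KneeNet}}.
#' @return character scalar.
#' @export
modelChecksum <- function(model) {
    v <- unlist(lapply(model@nodes, function(nd) c(nd$W, nd$b)),
                use.names = FALSE)
    sprintf("%d-%.10e", length(v), sum(v * seq_along(v) %% 97))
}

.qcFromKeypoints <- function(id, kps, decoded) {
    rec <- .qcRecord(id)
    flags <- character()
    res <- tryCatch({
        if (!is.null(decoded)) {
            rec$view_call <- decoded@viewCall
            vis <- decoded@keypoints@visible
            rec$mean_score <- mean(decoded@scores[vis])
            need <- if (decoded@viewCall == "AP") .AP_LABELS else KP_LABELS
            if (any(decoded@scores[need] < decoded@tau))
                flags <- c(flags, "low_confidence")
            computeQC(decoded)
        } else {
            rec$view_call <- kps@view
            computeQC(kps)
        }
    }, error = function(e) e)
    if (inherits(res, "error")) {
        flags <- c(flags, "degenerate_geometry")
    } else {
        rec$overlap_ratio <- res@overlapRatio
        rec$flexion_angle_deg <- res@flexionAngleDeg
        rec$normalized_flexion <- res@normalizedFlexion
        if (res@clamped) flags <- c(flags, "clamped_ratio")
    }
    rec$flags <- paste(flags, collapse = ";")
    rec
}
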