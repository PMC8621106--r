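#' Localization table
#'
#' The pipeline's central currency: one row per localized blinking event
#' (never per grouped molecule), with positions in nm from the ROI top-left
#' corner. A plain data.frame with columns `frame` (0-based), `x_nm`,
#' `y_nm`, `photons`, `sigma_nm`, `background`, plus metadata attributes.
#'
#' @param df data.frame with at least `frame`, `x_nm`, `y_nm`.
#' @param pixel_size_nm camera pixel size the data were acquired at.
#' @param frame_count number of frames in the source acquisition.
#' @param source free-text provenance tag.
#' @param roi_width_nm,roi_height_nm optional field-of-view extent in nm.
#' @return an object of class `localization_table` (also a data.frame).
#' @export
localization_table <- function(df, pixel_size_nm = NA_real_,
                               frame_count = NA_integer_, source = "",
                               roi_width_nm = NA_real_, roi_height_nm = NA_real_) {
  need <- c("frame", "x_nm", "y_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(
      paste0("localization table is missing mandatory column(s): ",
             paste(miss, collapse = ", ")),
      class = c("smlmpipe_format_error", "error")))
  }
  for (col in c("photons", "sigma_nm", "background")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (is.na(frame_count) && nrow(df) > 0) frame_count <- max(df$frame) + 1L
  structure(as.data.frame(df),
            pixel_size_nm = pixel_size_nm,
            frame_count = as.integer(frame_count),
            source = source,
            roi_width_nm = roi_width_nm, roi_height_nm = roi_height_nm,
            class = c("localization_table", "data.frame"))
}

#' @export
print.localization_table <- function(x, ...) {
  cat("localization_table:", nrow(x), "events over",
      attr(x, "frame_count"), "frames (source: ",
      attr(x, "source"), ")\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# rebuild class/attributes after subsetting operations strip them
as_localization_table <- function(df, template) {
  localization_table(as.data.frame(df),
                     pixel_size_nm = attr(template, "pixel_size_nm"),
                     frame_count = attr(template, "frame_count"),
                     source = attr(template, "source"),
                     roi_width_nm = attr(template, "roi_width_nm"),
                     roi_height_nm = attr(template, "roi_height_nm"))
}

# ROI extent in nm: metadata if present, else data bounding box
table_extent <- function(table) {
  w <- attr(table, "roi_width_nm"); h <- attr(table, "roi_height_nm")
  if (is.null(w) || is.na(w)) w <- if (nrow(table)) max(table$x_nm) else 0
  if (is.null(h) || is.na(h)) h <- if (nrow(table)) max(table$y_nm) else 0
  c(width_nm = w, height_nm = h)
}
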