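# FESGrid: regular 2-D free-energy surface over CV space, kJ/mol, with the
# global minimum anchored at 0. Rows index CV2, columns index CV1.

#' Free-energy surface on a regular 2-D grid
#'
#' @param values numeric matrix of free energies, kJ/mol. Rows index CV2,
#'   columns CV1.
#' @param cv1,cv2 strictly increasing, uniformly spaced axis coordinates
#'   (CV-units); lengths must match `ncol(values)` / `nrow(values)`.
#' @param temperature Kelvin.
#' @param metadata free-text provenance string.
#' @param anchor shift values so the global minimum is exactly 0
#'   (default TRUE; part of the class invariant).
#' @return object of class `fes_grid`.
#' @export
fes_grid <- function(values, cv1, cv2, temperature = 310,
                     metadata = "", anchor = TRUE) {
  stopifnot(is.matrix(values), all(is.finite(values)),
            length(cv1) == ncol(values), length(cv2) == nrow(values),
            temperature > 0)
  .check_uniform(cv1, "cv1")
  .check_uniform(cv2, "cv2")
  if (anchor) values <- values - min(values)
  structure(list(values = values, cv1 = as.numeric(cv1), cv2 = as.numeric(cv2),
                 temperature = temperature, metadata = metadata),
            class = "fes_grid")
}

.check_uniform <- function(x, name) {
  if (length(x) < 2) stop(name, " axis needs >= 2 points")
  d <- diff(x)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * abs(d[1]))
    stop(name, " axis must be strictly increasing with uniform spacing")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d (CV2 x CV1), F in [0, %.2f] kJ/mol, T = %g K\n",
              nrow(x$values), ncol(x$values), max(x$values), x$temperature))
  if (nzchar(x$metadata)) cat(" ", x$metadata, "\n")
  invisible(x)
}

#' Grid spacing of an fes_grid
#' @param grid an `fes_grid`.
#' @return c(cv1 spacing, cv2 spacing), CV-units.
#' @export
fes_spacing <- function(grid) {
  c(grid$cv1[2] - grid$cv1[1], grid$cv2[2] - grid$cv2[1])
}

#' Write / read an FES grid as a CSV matrix plus JSON sidecar
#'
#' The CSV holds the bare value matrix (rows = CV2, columns = CV1, no
#' headers). The JSON sidecar (`<path>.json`) records axis origins,
#' spacings, lengths, temperature, metadata, and the row/column convention.
#'
#' @param grid an `fes_grid`.
#' @param path CSV file path; the sidecar is written beside it.
#' @return `path`, invisibly.
#' @export
write_fes <- function(grid, path) {
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(cv1 = list(origin = grid$cv1[1], spacing = fes_spacing(grid)[1],
                          n = length(grid$cv1)),
               cv2 = list(origin = grid$cv2[1], spacing = fes_spacing(grid)[2],
                          n = length(grid$cv2)),
               temperature = grid$temperature, metadata = grid$metadata,
               layout = "rows = CV2, columns = CV1, 0-based indices in reports")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  cv1 <- side$cv1$origin + side$cv1$spacing * (seq_len(side$cv1$n) - 1)
  cv2 <- side$cv2$origin + side$cv2$spacing * (seq_len(side$cv2$n) - 1)
  fes_grid(vals, cv1, cv2, temperature = side$temperature,
           metadata = if (is.null(side$metadata)) "" else side$metadata)
}
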