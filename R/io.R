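#' Write / read an epoch set container
#'
#' Round-trip storage for [acc_epochs()] objects as an R serialization
#' container (one file per condition, as the cohort manifest expects).
#'
#' @param epochs an [acc_epochs()] object.
#' @param path file path.
#' @return `write_epoch_set()` returns `path` invisibly; `read_epoch_set()`
#'   returns the [acc_epochs()] object.
#' @export
write_epoch_set <- function(epochs, path) {
  stopifnot(inherits(epochs, "acc_epochs"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "acc_epochs")) stop("not an epoch-set container", call. = FALSE)
  obj
}

#' Read a recording from disk
#'
#' Entry point for stored data: either the package's epoch-set container
#' (`format = "container"`) or a continuous multichannel recording as CSV
#' with one column per channel (`format = "csv"`; column names must include
#' `Cz` and the mastoids, remappable via `channel_map`). The recording's
#' sampling rate is validated against the design.
#'
#' @param path file path.
#' @param format `"container"` or `"csv"`.
#' @param design an [acc_design()] the data must match.
#' @param fs sampling rate of a CSV recording, Hz (required for CSV).
#' @param channel_map optional named character vector mapping file column
#'   names to `c("Cz", "ipsi", "contra")`, e.g.
#'   `c(Cz = "EEG_CZ", ipsi = "M1", contra = "M2")`.
#' @return An [acc_epochs()] object (container) or a data frame of
#'   continuous channels in uV (csv).
#' @export
read_recording <- function(path, format = c("container", "csv"), design,
                           fs = NULL, channel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_design(design)
  if (format == "container") {
    ep <- read_epoch_set(path)
    if (ep$design$fs != design$fs) {
      stop("container sampling rate ", ep$design$fs,
           " Hz does not match design fs ", design$fs, " Hz", call. = FALSE)
    }
    return(ep)
  }
  if (is.null(fs)) stop("fs is required for CSV recordings", call. = FALSE)
  if (fs != design$fs) {
    stop("recording sampling rate ", fs, " Hz does not match design fs ",
         design$fs, " Hz", call. = FALSE)
  }
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(channel_map)) {
    missing_src <- setdiff(unname(channel_map), names(dat))
    if (length(missing_src)) {
      stop("channel(s) not in file: ", paste(missing_src, collapse = ", "),
           call. = FALSE)
    }
    for (dst in names(channel_map)) names(dat)[names(dat) == channel_map[[dst]]] <- dst
  }
  need <- c("Cz", "ipsi")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("required channel missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dat
}
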