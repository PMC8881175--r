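#' @title On-disk formats
#' @description Epoch sets are stored as a directory of per-epoch CSV
#'   files (channels x samples, one row per channel, full `%.17g`
#'   precision so a round trip is bit-identical) plus a `meta.json`
#'   sidecar holding `fs`, `t0`, `channel_ids` and the epoch count.
#'   Simulated studies add a `truth.csv` table and a `config.json`
#'   snapshot. Times are ms, potentials µV, sample indices 1-based,
#'   windows half-open — everywhere.
#' @name formats
NULL

fmt_num <- function(x) sprintf("%.17g", x)

write_epoch_csv <- function(epoch, path) {
  m <- apply(epoch$data, c(1, 2), fmt_num)
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = epoch$channel_ids, col.names = FALSE)
}

read_epoch_csv <- function(path, fs, t0, channel_ids) {
  raw <- utils::read.table(path, sep = ",", row.names = 1L,
                           colClasses = "character")
  data <- matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw))
  eeg_epoch(data, fs = fs, t0 = t0, channel_ids = channel_ids)
}

#' Write a list of epochs to a directory
#'
#' @param epochs Non-empty list of `eeg_epoch`s sharing geometry.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  if (length(epochs) == 0L) stop("'epochs' must be non-empty")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  e1 <- epochs[[1L]]
  meta <- list(fs = e1$fs, t0 = e1$t0, channel_ids = e1$channel_ids,
               n_epochs = length(epochs))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(epochs))
    write_epoch_csv(epochs[[i]], file.path(dir, sprintf("epoch_%04d.csv", i)))
  invisible(dir)
}

#' Load epochs from disk
#'
#' Reads the package's CSV-directory epoch format (see the formats help
#' page). EDF and BrainVision imports are not built in: convert such
#' recordings to the CSV format (any EEG toolchain can export a plain
#' channels-by-samples text matrix) before loading.
#'
#' @param path Directory written by [write_epochs()].
#' @param format Only `"csv"` is supported.
#' @return List of `eeg_epoch`s.
#' @export
load_epochs <- function(path, format = "csv") {
  if (format != "csv")
    stop("format '", format,
         "' is not supported; convert to the CSV epoch format")
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("missing sidecar ", meta_path, " (fs/t0/channel_ids are required)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "t0", "channel_ids", "n_epochs"))
    if (is.null(meta[[field]])) stop("sidecar is missing field '", field, "'")
  lapply(seq_len(meta$n_epochs), function(i) {
    f <- file.path(path, sprintf("epoch_%04d.csv", i))
    if (!file.exists(f)) stop("missing epoch file ", f)
    read_epoch_csv(f, meta$fs, meta$t0, meta$channel_ids)
  })
}

#' Write a simulated study to a directory
#'
#' Layout: `noise/` (the sigma = 0 control epochs), `cond_<amp>/` per
#' amplitude, `truth.csv`, and a `config.json` snapshot of the study
#' parameters.
#'
#' @param study An `erp_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_epochs(study$noise, file.path(dir, "noise"))
  truth <- list()
  for (cn in names(study$conditions)) {
    cond <- study$conditions[[cn]]
    write_epochs(cond$epochs, file.path(dir, paste0("cond_", cn)))
    truth[[cn]] <- cond$truth
  }
  utils::write.csv(do.call(rbind, truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- list(tau = study$tau, theta = study$theta, sign = study$sign,
              amplitudes = study$amplitudes,
              region = list(name = study$region$name,
                            channels = study$region$channels))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated study from a directory
#'
#' @param dir Directory written by [write_study()].
#' @return An `erp_study`.
#' @export
read_study <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  noise <- load_epochs(file.path(dir, "noise"))
  region <- region_spec(cfg$region$name, cfg$region$channels)
  conditions <- lapply(cfg$amplitudes, function(a) {
    epochs <- load_epochs(file.path(dir, paste0("cond_", a)))
    list(sigma = a,
         epochs = epochs,
         truth = data.frame(trial_id = seq_along(epochs), sigma = a,
                            tau = cfg$tau))
  })
  names(conditions) <- as.character(cfg$amplitudes)
  structure(list(noise = noise, conditions = conditions, region = region,
                 tau = cfg$tau, theta = cfg$theta, sign = cfg$sign,
                 amplitudes = cfg$amplitudes),
            class = "erp_study")
}
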