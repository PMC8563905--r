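#' Write a session bundle to a directory of plain-text files
#'
#' Layout: `photometry.csv` (t_s, f465, f405), `contacts.csv` (t_s),
#' `pose_profile.csv` (flat dialect: frame, jaw_x, jaw_y, jaw_likelihood,
#' tongue_x, tongue_y, tongue_likelihood; or the 3-header-row tracker
#' dialect), `stim.csv` (onset_s, width_s; only when a stimulus is
#' attached), `truth.yaml` and `config.yaml`. Numbers are written with full
#' precision so a fixed-seed bundle serializes byte-identically across runs.
#'
#' @param bundle a `session_bundle` from [generate_session()].
#' @param dir output directory (created if needed).
#' @param pose_dialect `"flat"` (default) or `"tracker"` (3 header rows:
#'   scorer / bodyparts / coords, as emitted by markerless trackers).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir, pose_dialect = c("flat", "tracker")) {
  pose_dialect <- match.arg(pose_dialect)
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) formatC(x, digits = 17, format = "g")
  ph <- bundle$photometry
  utils::write.csv(
    data.frame(t_s = num(ts_time(ph$f465)), f465 = num(ph$f465$values),
               f405 = num(ph$f405$values)),
    file.path(dir, "photometry.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(t_s = num(ph$contacts$times_s)),
                   file.path(dir, "contacts.csv"),
                   row.names = FALSE, quote = FALSE)
  write_pose_table(bundle$pose$jaw, bundle$pose$tongue,
                   file.path(dir, "pose_profile.csv"), pose_dialect)
  if (!is.null(bundle$stim))
    utils::write.csv(
      data.frame(onset_s = num(bundle$stim$onsets_s),
                 width_s = num(rep(bundle$stim$width_s,
                                   length(bundle$stim$onsets_s)))),
      file.path(dir, "stim.csv"), row.names = FALSE, quote = FALSE)
  writeLines(yaml::as.yaml(serialize_numbers(bundle$truth)),
             file.path(dir, "truth.yaml"))
  cfg <- bundle$config
  cfg_list <- list(
    duration_s = cfg$duration_s, raw_rate_hz = cfg$raw_rate_hz,
    video_rate_hz = cfg$video_rate_hz, lapping_rate_hz = cfg$lapping_rate_hz,
    bout_structure = list(start_s = cfg$bout_structure$start_s,
                          n_licks = cfg$bout_structure$n_licks),
    contact_to_peak_delay_s = cfg$contact_to_peak_delay_s,
    kernel = unclass(cfg$kernel),
    bleach_tau_s = cfg$bleach_tau_s, motion_amp = cfg$motion_amp,
    noise_sd = cfg$noise_sd, scale_bar_px = cfg$scale_bar_px,
    seed = cfg$seed,
    session_id = ph$session_id, animal_id = ph$animal_id)
  writeLines(yaml::as.yaml(serialize_numbers(cfg_list)),
             file.path(dir, "config.yaml"))
  invisible(dir)
}

# internal: encode doubles as full-precision strings so YAML round-trips
# exactly; deserialize_numbers() is the inverse
serialize_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, serialize_numbers))
  if (is.double(x)) return(formatC(x, digits = 17, format = "g"))
  x
}

deserialize_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, deserialize_numbers))
  if (is.character(x)) {
    v <- suppressWarnings(as.numeric(x))
    if (length(x) && !anyNA(v)) return(v)
  }
  x
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return a `session_bundle` equivalent to the one written (stimulus and
#'   ground truth included when present).
#' @export
read_session <- function(dir) {
  ph <- utils::read.csv(file.path(dir, "photometry.csv"))
  cfgl <- deserialize_numbers(yaml::read_yaml(file.path(dir, "config.yaml")))
  rate <- cfgl$raw_rate_hz
  contacts_df <- utils::read.csv(file.path(dir, "contacts.csv"))
  pose <- read_pose_table(file.path(dir, "pose_profile.csv"),
                          rate_hz = cfgl$video_rate_hz)
  stim_path <- file.path(dir, "stim.csv")
  stim <- NULL
  if (file.exists(stim_path)) {
    sdf <- utils::read.csv(stim_path)
    if (nrow(sdf)) stim <- stim_train(sdf$onset_s, sdf$width_s[1])
  }
  truth <- deserialize_numbers(yaml::read_yaml(file.path(dir, "truth.yaml")))
  kern <- do.call(calcium_kernel, cfgl$kernel[c("shape", "width_s",
                                               "tau_rise_s", "tau_decay_s",
                                               "amplitude")])
  config <- generator_config(
    duration_s = cfgl$duration_s, raw_rate_hz = cfgl$raw_rate_hz,
    video_rate_hz = cfgl$video_rate_hz,
    lapping_rate_hz = cfgl$lapping_rate_hz,
    bout_structure = data.frame(start_s = unlist(cfgl$bout_structure$start_s),
                                n_licks = unlist(cfgl$bout_structure$n_licks)),
    contact_to_peak_delay_s = cfgl$contact_to_peak_delay_s,
    kernel = kern, bleach_tau_s = cfgl$bleach_tau_s,
    motion_amp = cfgl$motion_amp, noise_sd = cfgl$noise_sd,
    scale_bar_px = cfgl$scale_bar_px, seed = cfgl$seed)
  structure(
    list(
      photometry = list(
        f465 = ts_signal(ph$f465, rate, ph$t_s[1]),
        f405 = ts_signal(ph$f405, rate, ph$t_s[1]),
        contacts = event_series(contacts_df$t_s, "contact"),
        session_id = cfgl$session_id, animal_id = cfgl$animal_id),
      pose = pose[c("jaw", "tongue")],
      stim = stim,
      truth = truth,
      config = config),
    class = "session_bundle")
}

#' Write jaw and tongue tracks as a pose CSV
#'
#' @param jaw,tongue [pose_track()]s on a common frame grid.
#' @param path output file.
#' @param dialect `"flat"` or `"tracker"` (3-header-row scorer/bodyparts/
#'   coords layout).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(jaw, tongue, path, dialect = c("flat", "tracker")) {
  dialect <- match.arg(dialect)
  num <- function(x) formatC(x, digits = 17, format = "g")
  n <- length(jaw$y)
  stopifnot(length(tongue$y) == n)
  if (dialect == "flat") {
    utils::write.csv(
      data.frame(frame = seq_len(n) - 1L,
                 jaw_x = num(jaw$x), jaw_y = num(jaw$y),
                 jaw_likelihood = num(jaw$likelihood),
                 tongue_x = num(tongue$x), tongue_y = num(tongue$y),
                 tongue_likelihood = num(tongue$likelihood)),
      path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- c(
      paste(c("scorer", rep("synthetic", 6)), collapse = ","),
      paste(c("bodyparts", rep(c("jaw", "tongue"), each = 3)), collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), 2)), collapse = ","))
    body <- paste(seq_len(n) - 1L,
                  num(jaw$x), num(jaw$y), num(jaw$likelihood),
                  num(tongue$x), num(tongue$y), num(tongue$likelihood),
                  sep = ",")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a pose CSV in either the flat or the tracker dialect
#'
#' The dialect is auto-detected: a first cell of `scorer` marks the
#' 3-header-row layout (scorer / bodyparts / coords) produced by markerless
#' trackers; otherwise a flat header
#' `frame, jaw_x, jaw_y, jaw_likelihood, tongue_x, tongue_y,
#' tongue_likelihood` is expected.
#'
#' @param path pose CSV file.
#' @param rate_hz frame rate to attach to the tracks (default 120).
#' @return list with [pose_track()]s `jaw` and `tongue` (pixel units) and
#'   the detected `dialect`.
#' @export
read_pose_table <- function(path, rate_hz = 120) {
  first <- readLines(path, n = 1L)
  tracker <- startsWith(first, "scorer")
  if (tracker) {
    hdr2 <- strsplit(readLines(path, n = 2L)[2], ",")[[1]]
    hdr3 <- strsplit(readLines(path, n = 3L)[3], ",")[[1]]
    df <- utils::read.csv(path, skip = 3, header = FALSE)
    cols <- paste(hdr2[-1], hdr3[-1], sep = "_")
    names(df) <- c("frame", cols)
  } else {
    df <- utils::read.csv(path)
  }
  need <- c("jaw_x", "jaw_y", "jaw_likelihood",
            "tongue_x", "tongue_y", "tongue_likelihood")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pose table lacks column(s): ", paste(miss, collapse = ", "))
  list(
    jaw = pose_track(df$jaw_x, df$jaw_y, df$jaw_likelihood, rate_hz,
                     "jaw", "px"),
    tongue = pose_track(df$tongue_x, df$tongue_y, df$tongue_likelihood,
                        rate_hz, "tongue", "px"),
    dialect = if (tracker) "tracker" else "flat")
}
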