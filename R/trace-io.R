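# Sweep / episodic-recording containers and the native on-disk format
# (one CSV per sweep plus a JSON sidecar carrying protocol metadata).

#' Construct a single sweep
#'
#' A sweep is one sampled trace (voltage in mV or current in pA) together
#' with a description of the command waveform that elicited it. Time is
#' sweep-relative in seconds, sample 0 at t = 0.
#'
#' @param samples Numeric vector, mV (voltage channel) or pA (current
#'   channel); all values must be finite.
#' @param sampling_rate Samples per second (Hz), > 0.
#' @param channel `"voltage"` or `"current"`: the recorded quantity.
#' @param command List describing the command waveform. Supported shapes:
#'   `list(type = "step", amplitude =, onset =, duration =)` (amplitude in
#'   pA for current-clamp or mV for voltage-clamp commands, onset/duration
#'   in s), `list(type = "ramp", from =, to =, onset =, duration =)` (mV),
#'   or `list(type = "gapfree")`.
#' @param index Sweep index within its recording (1-based).
#' @return Object of class `ck_sweep`.
#' @export
sweep_trace <- function(samples, sampling_rate, channel = c("voltage", "current"),
                        command = list(type = "gapfree"), index = 1L) {
  channel <- match.arg(channel)
  if (!is.numeric(samples) || length(samples) == 0)
    stop("sweep_trace: samples must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("sweep_trace: all samples must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sweep_trace: sampling_rate must be > 0")
  dur <- length(samples) / sampling_rate
  if (!is.list(command) || is.null(command$type))
    stop("sweep_trace: command must be a list with a 'type' field")
  if (command$type %in% c("step", "ramp")) {
    cmd_end <- (command$onset %||% 0) + (command$duration %||% 0)
    if (cmd_end > dur + 1e-9)
      stop("sweep_trace: command extends past the end of the trace")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 channel = channel, command = command,
                 index = as.integer(index)),
            class = "ck_sweep")
}

#' Time axis of a sweep (s)
#' @param sweep A [sweep_trace()].
#' @return Numeric vector of sample times, starting at 0.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1) / sweep$sampling_rate
}

#' @export
print.ck_sweep <- function(x, ...) {
  cat(sprintf("<ck_sweep> %s, %d samples @ %g kHz, command %s\n",
              x$channel, length(x$samples), x$sampling_rate / 1000,
              x$command$type))
  invisible(x)
}

#' Construct an episodic recording
#'
#' An ordered family of sweeps acquired under one protocol from one cell,
#' with the metadata the analysis stages need: protocol description, cell
#' and group identity, junction potential and correction state, whole-cell
#' capacitance and access resistance.
#'
#' @param sweeps List of [sweep_trace()] objects sharing sampling rate and
#'   channel kind.
#' @param protocol List with at least `mode` (`"current_step"`,
#'   `"voltage_step"`, `"voltage_ramp"`, `"prepulse"` or `"gapfree"`); step
#'   protocols carry `step_increment` and the per-sweep command levels are
#'   taken from the sweeps themselves.
#' @param cell_id Cell identifier (unique within a study).
#' @param group Group label (e.g. genotype).
#' @param junction_potential Liquid junction potential (mV) applicable to
#'   the recording.
#' @param corrected Has the junction correction already been applied?
#' @param capacitance Whole-cell capacitance (pF) or NA.
#' @param access_resistance Access resistance (MOhm) or NA.
#' @param input_resistance Input resistance (MOhm) or NA (used by
#'   nucleated-patch QC, where it is measured in GOhm range).
#' @return Object of class `ck_recording`.
#' @export
episodic_recording <- function(sweeps, protocol = list(mode = "gapfree"),
                               cell_id = "cell", group = "",
                               junction_potential = 0, corrected = FALSE,
                               capacitance = NA_real_,
                               access_resistance = NA_real_,
                               input_resistance = NA_real_) {
  if (length(sweeps) == 0) stop("episodic_recording: no sweeps")
  if (!all(vapply(sweeps, inherits, logical(1), "ck_sweep")))
    stop("episodic_recording: sweeps must be ck_sweep objects")
  rates <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  chans <- vapply(sweeps, function(s) s$channel, character(1))
  if (length(unique(rates)) != 1)
    stop("episodic_recording: sweeps must share one sampling rate")
  if (length(unique(chans)) != 1)
    stop("episodic_recording: sweeps must share one channel kind")
  amps <- command_levels(sweeps)
  if (length(amps) > 2 && !anyNA(amps)) {
    incs <- round(diff(amps), 9)
    if (length(unique(incs)) > 1)
      stop("episodic_recording: step increments are not uniform")
  }
  structure(list(sweeps = sweeps, protocol = protocol, cell_id = cell_id,
                 group = group, junction_potential = junction_potential,
                 corrected = corrected, capacitance = capacitance,
                 access_resistance = access_resistance,
                 input_resistance = input_resistance),
            class = "ck_recording")
}

# per-sweep command step levels (pA or mV); NA where not a step
command_levels <- function(sweeps) {
  vapply(sweeps, function(s)
    if (identical(s$command$type, "step")) s$command$amplitude else NA_real_,
    numeric(1))
}

#' @export
print.ck_recording <- function(x, ...) {
  cat(sprintf("<ck_recording> cell '%s'%s: %d %s sweeps (%s), %scorrected\n",
              x$cell_id,
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
              length(x$sweeps), x$sweeps[[1]]$channel, x$protocol$mode,
              if (x$corrected) "" else "un"))
  invisible(x)
}

#' Write an episodic recording in the native format
#'
#' The native container is a directory holding `recording.json` (protocol,
#' sampling rate, units, identity, correction state, and any ground-truth
#' payload attached by a simulator) plus one `sweep_NNN.csv` per sweep with
#' a single `samples` column printed at full double precision, so a
#' write/read round trip reproduces samples bit-for-bit. Only the native
#' format is written; ABF output is refused.
#'
#' @param recording A [episodic_recording()].
#' @param path Directory to create/overwrite.
#' @param format Must be `"native"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = "native") {
  stopifnot(inherits(recording, "ck_recording"))
  if (!identical(format, "native"))
    stop("write_recording: only the native CSV+JSON format is written; ",
         "ABF output is not supported")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("write_recording: cannot create ", path)
  meta <- list(
    container = "clampkit-native-v1",
    n_sweeps = length(recording$sweeps),
    sampling_rate = recording$sweeps[[1]]$sampling_rate,
    channel = recording$sweeps[[1]]$channel,
    units = if (recording$sweeps[[1]]$channel == "voltage") "mV" else "pA",
    protocol = recording$protocol,
    cell_id = recording$cell_id,
    group = recording$group,
    junction_potential = recording$junction_potential,
    corrected = recording$corrected,
    capacitance = recording$capacitance,
    access_resistance = recording$access_resistance,
    input_resistance = recording$input_resistance,
    commands = lapply(recording$sweeps, function(s) s$command),
    ground_truth = attr(recording, "ground_truth"))
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (i in seq_along(recording$sweeps)) {
    f <- file.path(path, sprintf("sweep_%03d.csv", i))
    con <- file(f, "w")
    writeLines("samples", con)
    writeLines(sprintf("%.17g", recording$sweeps[[i]]$samples), con)
    close(con)
  }
  invisible(path)
}

#' Read an episodic recording
#'
#' Reads the native CSV+JSON container written by [write_recording()].
#' Units are normalized to mV / pA / s. Axon Binary Format is recognized by
#' extension but not supported; requesting it raises an informative error
#' rather than guessing at the file contents.
#'
#' @param path Directory of a native recording (or an `.abf` path, which
#'   errors).
#' @param format `"native"` (default) or `"abf"`.
#' @return A [episodic_recording()]; any simulator ground truth is restored
#'   in `attr(, "ground_truth")`.
#' @export
read_recording <- function(path, format = c("native", "abf")) {
  format <- match.arg(format)
  if (format == "abf" || grepl("\\.abf$", path, ignore.case = TRUE))
    stop("read_recording: ABF input is not supported by this build; ",
         "convert to the native CSV+JSON container (", path, ")")
  sidecar <- file.path(path, "recording.json")
  if (!dir.exists(path))
    stop("read_recording: no such recording directory: ", path)
  if (!file.exists(sidecar))
    stop("read_recording: missing JSON sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (!identical(meta$container, "clampkit-native-v1"))
    stop("read_recording: ", sidecar, " is not a clampkit native recording")
  sweeps <- vector("list", meta$n_sweeps)
  for (i in seq_len(meta$n_sweeps)) {
    f <- file.path(path, sprintf("sweep_%03d.csv", i))
    if (!file.exists(f)) stop("read_recording: missing sweep file ", f)
    samples <- scan(f, what = double(), skip = 1, quiet = TRUE)
    sweeps[[i]] <- sweep_trace(samples, meta$sampling_rate,
                               channel = meta$channel,
                               command = meta$commands[[i]], index = i)
  }
  rec <- episodic_recording(
    sweeps, protocol = meta$protocol, cell_id = meta$cell_id,
    group = meta$group %||% "",
    junction_potential = meta$junction_potential %||% 0,
    corrected = isTRUE(meta$corrected),
    capacitance = null2na(meta$capacitance),
    access_resistance = null2na(meta$access_resistance),
    input_resistance = null2na(meta$input_resistance))
  attr(rec, "ground_truth") <- meta$ground_truth
  rec
}

null2na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)

#' Apply the liquid-junction-potential correction
#'
#' Shifts every voltage sample and every voltage command by minus the
#' junction potential, marking the recording corrected. Correcting twice is
#' an error, so pipelines can require corrected recordings without risking
#' a silent double shift. Current-channel samples are untouched; voltage
#' commands of voltage-clamp protocols are shifted along with the data.
#'
#' @param recording A [episodic_recording()] with `corrected = FALSE`.
#' @param ljp Junction potential (mV) to subtract; defaults to the value
#'   stored in the recording.
#' @return The corrected recording.
#' @export
apply_junction_correction <- function(recording, ljp = NULL) {
  stopifnot(inherits(recording, "ck_recording"))
  if (isTRUE(recording$corrected))
    stop("apply_junction_correction: recording is already corrected")
  ljp <- ljp %||% recording$junction_potential
  recording$sweeps <- lapply(recording$sweeps, function(s) {
    if (s$channel == "voltage") s$samples <- s$samples - ljp
    if (s$command$type == "step" && s$channel == "current") {
      # voltage-clamp command stored on a current channel sweep is in mV
      if (isTRUE(s$command$unit == "mV"))
        s$command$amplitude <- s$command$amplitude - ljp
    } else if (s$command$type == "ramp") {
      s$command$from <- s$command$from - ljp
      s$command$to <- s$command$to - ljp
    }
    s
  })
  recording$junction_potential <- ljp
  recording$corrected <- TRUE
  recording
}
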