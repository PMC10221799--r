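#' Pipeline configuration
#'
#' Bundles the per-stage configurations with one global seed that
#' propagates to every stochastic stage, so a pipeline run is fully
#' deterministic.
#'
#' @param synth A [synth_config()] (its `seed` is overridden by `seed`).
#' @param frontend A [frontend_config()].
#' @param adc An [adc_config()].
#' @param frame A [frame_spec()].
#' @param fatigue A [fatigue_params()].
#' @param gesture A list of [run_gesture_pipeline()] arguments
#'   (`n_trials_per_class`, `separability`, `train_frac`, `variance_keep`,
#'   `kernel`, `cost`).
#' @param seed Global integer seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            frontend = frontend_config(),
                            adc = adc_config(),
                            frame = frame_spec(),
                            fatigue = fatigue_params(),
                            gesture = list(),
                            seed = 1L) {
  stopifnot(inherits(synth, "synth_config"),
            inherits(frontend, "frontend_config"),
            inherits(adc, "adc_config"),
            inherits(frame, "frame_spec"),
            inherits(fatigue, "fatigue_params"))
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, frontend = frontend, adc = adc,
                 frame = frame, fatigue = fatigue, gesture = gesture,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end digital twin
#'
#' `characterize` mode evaluates the analog design: it writes the Bode
#' table and a design-check report (passband gain product, the -3 dB and
#' stopband points of the low-pass, the notch rejection).  `fatigue` mode
#' runs generation, the analog cascade, ADC framing/decoding and the
#' fatigue analysis; `gesture` mode runs the four-class recognition
#' pipeline.  Reports are JSON plus CSV tables; a manifest lists every
#' output with its MD5 content hash.  Given the same configuration the
#' reports are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param mode One of `"fatigue"`, `"gesture"`, `"characterize"`.
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, the report as a list (also written to
#'   `<mode>_report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("fatigue", "gesture", "characterize"),
                         out_dir = ".") {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  report <- switch(
    mode,
    characterize = {
      tbl <- bode_table(config$frontend)
      bode_path <- file.path(out_dir, "bode.csv")
      utils::write.csv(tbl, bode_path, row.names = FALSE)
      files <- c(files, bode_path)
      fe <- config$frontend
      s2 <- tf_stage2(fe)
      casc <- tf_frontend(fe)
      list(
        passband_gain_product = fe$g1 * fe$g2 * fe$g3,
        cascade_gain_150hz = abs(tf_eval(casc, 150)),
        lp_cutoff_db = db(abs(tf_eval(s2, fe$f_lp)) / fe$g2),
        lp_stopband_1600hz_db = db(abs(tf_eval(s2, 1600)) / fe$g2),
        notch_rejection_db = max(
          db(Mod(tf_eval(casc, c(49.5, 50.5))) / abs(tf_eval(casc, 150)))),
        throughput_bps = throughput(config$adc, config$frame))
    },
    fatigue = {
      res <- run_fatigue_pipeline(config)
      g <- glance(res$report)
      c(list(packet_loss_rate = res$decode$packet_loss_rate,
             frames_ok = res$decode$frames_ok,
             rms_slopes = res$report$fits$rms_slope),
        as.list(g))
    },
    gesture = {
      res <- rlang::exec(run_gesture_pipeline, seed = config$seed,
                         !!!config$gesture)
      list(accuracy = res$accuracy,
           recall = as.numeric(res$confusion$recall),
           confusion = unname(apply(res$confusion$table, 1, as.list)))
    })
  report_path <- file.path(out_dir, paste0(mode, "_report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, report_path)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' Fatigue twin: generation through analysis
#'
#' Runs one fatigue session through the whole acquisition model: synthetic
#' generation at the synthesis rate, the three-stage analog cascade,
#' decimating quantization to the ADC rate, frame encoding and decoding,
#' reconstruction to volts and the fatigue analysis.
#'
#' @param config A [pipeline_config()] whose `synth` element describes the
#'   session (see [fatigue_session_config()]).
#' @return A list with the decoded `trace`, the [decode_stream()] report
#'   (`decode`) and the [fatigue_report()] (`report`).
#' @export
run_fatigue_pipeline <- function(config = pipeline_config(
                                   synth = fatigue_session_config())) {
  raw_trace <- generate_semg(config$synth)
  conditioned <- apply_frontend(raw_trace, config$frontend)
  codes <- quantize(conditioned, config$adc)
  stream <- encode_stream(codes, config$frame)
  decoded <- decode_stream(stream, config$frame)
  volts <- dequantize(decoded$samples, config$adc)
  trace <- new_emg_trace(volts, config$adc$fs_adc)
  list(trace = trace, decode = decoded,
       report = fatigue_report(trace, config$fatigue))
}
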