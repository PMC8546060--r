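kinetics_export_cols <- function() {
  pars <- c("max_fs", "v_con_20", "v_con_50", "v_con_80", "v_rel_80",
            "v_rel_50", "v_rel_20", "peak_acceleration",
            "deceleration_time", "relaxation_time")
  c("tissue_id", "n_beats", "frequency_hz", pars, paste0(pars, "_sd"))
}

#' Write a per-tissue kinetics table with a provenance sidecar
#'
#' One row per tissue: every exported kinetic parameter and its per-beat
#' standard deviation, as CSV. A JSON sidecar (`<path>.json`) records the
#' configuration and provenance (software version, optional seed, time).
#'
#' @param records named list of `kinetics_summary` objects (names become
#'   `tissue_id`); may be empty (header-only CSV).
#' @param path output CSV path.
#' @param config optional list stored in the sidecar.
#' @param seed optional integer stored in the sidecar.
#' @return `path`, invisibly.
#' @seealso [read_kinetics_table()]
#' @export
write_kinetics_table <- function(records, path, config = list(),
                                 seed = NULL) {
  cols <- kinetics_export_cols()
  rows <- lapply(seq_along(records), function(i) {
    ks <- records[[i]]
    id <- names(records)[i] %||% as.character(i)
    if (is.null(names(records)) || !nzchar(id)) id <- as.character(i)
    pars <- c("max_fs", "v_con_20", "v_con_50", "v_con_80", "v_rel_80",
              "v_rel_50", "v_rel_20", "peak_acceleration",
              "deceleration_time", "relaxation_time")
    vals <- vapply(pars, function(p) ks[[p]], numeric(1))
    sds <- ks$sd[pars]
    df <- data.frame(tissue_id = id, n_beats = ks$n_beats,
                     frequency_hz = ks$frequency, t(vals), t(sds))
    names(df) <- cols
    df
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  write.csv(tab, path, row.names = FALSE)
  side <- list(software = "mbkit",
               version = as.character(utils::packageVersion("mbkit")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               n_records = length(records), config = config)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kinetics table written by [write_kinetics_table()]
#' @param path CSV path.
#' @return Data frame; the sidecar, if present, is attached as attribute
#'   `"provenance"`.
#' @export
read_kinetics_table <- function(path) {
  tab <- read.csv(path, colClasses = c(tissue_id = "character"))
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(tab, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab
}
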