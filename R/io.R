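.default_config <- function() {
  list(
    rates = list(Tx = 1, Ty = 1),
    seed = 1L,
    sweep = list(parameter = "Tx", fixed_value = 0.5,
                 grid = list(min = 0.5, max = 8, n = 201L, log = TRUE)),
    phase = list(Tx = list(min = 0.5, max = 8, n = 61L, log = TRUE),
                 Ty = list(min = 0.05, max = 4, n = 61L, log = TRUE)),
    basins = list(resolution = 21L),
    tolerances = list(fp = 1e-12, field = 1e-10, eig = 1e-8),
    output = list(dir = ".", timestamp = TRUE)
  )
}

.grid_from_spec <- function(g, name) {
  for (k in c("min", "max", "n"))
    if (is.null(g[[k]])) stop(sprintf("grid '%s' needs '%s'", name, k),
                              call. = FALSE)
  if (g$min <= 0 || g$max <= g$min || g$n < 2)
    stop(sprintf("grid '%s' must have 0 < min < max and n >= 2", name),
         call. = FALSE)
  if (isTRUE(g$log)) exp(seq(log(g$min), log(g$max), length.out = g$n))
  else seq(g$min, g$max, length.out = g$n)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the documented schema,
#' and fills defaults.  Exactly one of `yields` (keys `G_h`, `G_o`, `L`) or
#' `matrices` (keys `A`, `B`, each a row-major 2x2 list) must be present;
#' unknown keys anywhere in the schema are an error, not a warning.
#'
#' Recognised top-level keys: `yields` | `matrices`, `rates` (`Tx`, `Ty`),
#' `seed`, `sweep` (`parameter`, `fixed_value`, `grid` = `min`/`max`/`n`/
#' `log`), `phase` (`Tx`, `Ty` grids), `basins` (`resolution`),
#' `tolerances` (`fp`, `field`, `eig`), `output` (`dir`, `timestamp`).
#'
#' @param path path to a YAML file.
#' @return A list of class `"run_config"` with the effective parameters and
#'   a ready-built `game` ([bimatrix_game()]) element.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("yields", "matrices", "rates", "seed", "sweep", "phase",
             "basins", "tolerances", "output")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$yields) && !is.null(raw$matrices))
    stop("config must contain exactly one of 'yields' or 'matrices', not both",
         call. = FALSE)
  if (is.null(raw$yields) && is.null(raw$matrices))
    stop("config must contain one of 'yields' or 'matrices'", call. = FALSE)

  cfg <- utils::modifyList(.default_config(), raw)
  sub_known <- list(yields = c("G_h", "G_o", "L"), matrices = c("A", "B"),
                    rates = c("Tx", "Ty"),
                    sweep = c("parameter", "fixed_value", "grid"),
                    phase = c("Tx", "Ty"), basins = "resolution",
                    tolerances = c("fp", "field", "eig"),
                    output = c("dir", "timestamp"))
  for (nm in names(sub_known)) {
    bad <- setdiff(names(raw[[nm]]), sub_known[[nm]])
    if (length(bad))
      stop(sprintf("unknown key(s) under '%s': %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (tl in names(cfg$tolerances))
    .check_scalar(cfg$tolerances[[tl]], paste0("tolerances.", tl),
                  positive = TRUE)

  if (!is.null(raw$matrices)) {
    tom <- function(m, nm) {
      m <- tryCatch(matrix(as.numeric(unlist(m)), 2, 2, byrow = TRUE),
                    warning = function(w) stop("bad matrix ", nm,
                                               call. = FALSE))
      m
    }
    cfg$game <- bimatrix_game(tom(raw$matrices$A, "A"),
                              tom(raw$matrices$B, "B"))
    cfg$yields <- NULL
  } else {
    y <- do.call(metabolic_yields, cfg$yields)
    cfg$yields <- y
    cfg$game <- build_symbiosis_game(y)
  }
  cfg$rates <- exploration_rates(cfg$rates$Tx, cfg$rates$Ty)
  cfg$sweep$grid_values <- .grid_from_spec(cfg$sweep$grid, "sweep")
  cfg$phase$Tx_values <- .grid_from_spec(cfg$phase$Tx, "phase.Tx")
  cfg$phase$Ty_values <- .grid_from_spec(cfg$phase$Ty, "phase.Ty")
  if (!cfg$sweep$parameter %in% c("Tx", "Ty"))
    stop("sweep.parameter must be 'Tx' or 'Ty'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' Writes the effective parameters of a [load_config()] result (or a plain
#' list in the same schema) so that reloading reproduces them exactly.
#'
#' @param config a `"run_config"` or compatible list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(rates = list(Tx = config$rates$Tx, Ty = config$rates$Ty),
              seed = config$seed,
              sweep = config$sweep[c("parameter", "fixed_value", "grid")],
              phase = list(Tx = config$phase$Tx, Ty = config$phase$Ty),
              basins = config$basins,
              tolerances = config$tolerances,
              output = config$output)
  if (!is.null(config$yields)) {
    out$yields <- list(G_h = config$yields$G_h, G_o = config$yields$G_o,
                       L = config$yields$L)
  } else {
    out$matrices <- list(
      A = lapply(1:2, function(i) as.numeric(config$game$A[i, ])),
      B = lapply(1:2, function(i) as.numeric(config$game$B[i, ])))
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a results table as TSV with a commented metadata header
#'
#' Tab-separated values with a header row, preceded by `#`-prefixed metadata
#' lines (package version, seed, parameter echo, optional timestamp).
#' Floats are written in scientific notation with 12 digits after the
#' point, so a reload with [read_table_tsv()] reproduces values to better
#' than `1e-12` relative.
#'
#' @param records a data frame.
#' @param path output path.
#' @param meta named list echoed into the metadata header (e.g. `seed`,
#'   parameters); scalar values only.
#' @param timestamp include a timestamp line (suppress for byte-identical
#'   reruns).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, meta = list(), timestamp = TRUE) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metabogame %s",
                     as.character(utils::packageVersion("metabogame"))), con)
  if (timestamp)
    writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(meta[[nm]], digits = 12), collapse = " ")),
               con)
  fmt <- records
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- formatC(fmt[[j]], digits = 12, format = "e")
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path path to a TSV written by [write_table()].
#' @return A data frame (metadata lines skipped); the `meta` attribute holds
#'   the raw metadata lines.
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  out <- utils::read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                           stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}
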