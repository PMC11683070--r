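#' @useDynLib riceNsat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Column layout of a plot-observation table.  One row per destructive
# sampling event; leaf columns are Dualex indices for leaves-from-top 1-5.
.id_cols <- c("site", "variety", "subspecies", "n_rate", "stage",
              "biomass_w", "lnc", "pnc")
.leaf_cols <- c(paste0("chl_l", 1:5), paste0("flav_l", 1:5),
                paste0("nbi_l", 1:5))
.dataset_cols <- c(.id_cols, .leaf_cols, "leaf5_imputed")

#' Growth-stage codes
#'
#' Ordered rice growth stages used throughout the package: tillering (TI),
#' stem elongation (SE), panicle initiation (PI), heading (HD) and grain
#' filling (GF).
#' @export
rice_stages <- c("TI", "SE", "PI", "HD", "GF")

#' Channel-by-position feature names
#'
#' The 18 model input variables: each sensor channel (Chl, Flav, NBI) at
#' leaf positions 1-5 plus its across-leaf mean.  Names are stable so that
#' attribution reports are comparable across runs.
#' @export
feature_names <- c(
  paste0("Chl_L", 1:5), "Chl_mean",
  paste0("Flav_L", 1:5), "Flav_mean",
  paste0("NBI_L", 1:5), "NBI_mean"
)

#' Average the three within-leaf measurement positions
#'
#' A leaf-clip reading is taken at the middle, upper one-third and lower
#' one-third of the leaf blade; the leaf-level value is their arithmetic
#' mean.
#'
#' @param middle,upper_third,lower_third single readings, finite and > 0.
#' @return The leaf-level value (arithmetic mean of the three positions).
#' @export
average_positions <- function(middle, upper_third, lower_third) {
  v <- c(middle, upper_third, lower_third)
  if (length(v) != 3L || !all(is.finite(v)) || any(v <= 0))
    stop("invalid measurement: all three positions must be finite and > 0",
         call. = FALSE)
  mean(v)
}

#' Impute the fifth leaf from leaves 1-4
#'
#' Early in the season a shoot may not yet carry five fully expanded
#' leaves.  When only leaves 1-4 are available the fifth-leaf value is
#' imputed as their arithmetic mean.  Imputation is applied per channel
#' (Chl and Flav separately) and NBI is recomputed from the imputed
#' channels, so the NBI = Chl/Flav identity is preserved.
#'
#' @param readings_1_to_4 numeric vector of exactly four finite leaf values
#'   (positions 1-4).
#' @return The imputed leaf-5 value, with attribute `imputed = TRUE`.
#' @export
impute_fifth_leaf <- function(readings_1_to_4) {
  if (length(readings_1_to_4) != 4L || !all(is.finite(readings_1_to_4)))
    stop("insufficient leaves: need exactly 4 finite values for positions 1-4",
         call. = FALSE)
  structure(mean(readings_1_to_4), imputed = TRUE)
}

#' Nitrogen Balance Index
#'
#' NBI is the ratio of the chlorophyll to the flavonoid index.  It rises
#' under nitrogen surplus (high Chl, low Flav) and falls under deficiency.
#'
#' @param chl chlorophyll index (unitless).
#' @param flav flavonoid index (unitless), must be > 0.
#' @return `chl / flav`, vectorised.
#' @export
compute_nbi <- function(chl, flav) {
  if (any(!is.finite(flav)) || any(flav <= 0))
    stop("degenerate denominator: flav must be finite and > 0", call. = FALSE)
  chl / flav
}

#' Validate a plot-observation table
#'
#' Checks the documented schema: all columns present, positive biomass,
#' PNC and sensor channels, stages drawn from [rice_stages], NBI equal to
#' Chl/Flav within tolerance, and unique (site, variety, n_rate, stage)
#' keys up to replicates.
#'
#' @param obs a data.frame/data.table of plot observations.
#' @param check_nbi verify nbi == chl/flav to 1e-9 relative (default TRUE).
#' @return `obs` invisibly (as a data.table), or an error.
#' @export
validate_observations <- function(obs, check_nbi = TRUE) {
  obs <- data.table::as.data.table(obs)
  missing <- setdiff(.dataset_cols, names(obs))
  if (length(missing))
    stop("schema error: missing columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(obs) == 0L) return(invisible(obs))
  if (!all(obs$stage %in% rice_stages))
    stop("unknown growth stage code", call. = FALSE)
  num <- c("n_rate", "biomass_w", "lnc", "pnc", .leaf_cols)
  for (cl in num) {
    v <- obs[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-finite values in column ", cl, call. = FALSE)
  }
  if (any(obs$n_rate < 0)) stop("negative nitrogen rate", call. = FALSE)
  if (any(obs$biomass_w <= 0)) stop("non-positive biomass", call. = FALSE)
  if (any(obs$pnc <= 0)) stop("non-positive PNC", call. = FALSE)
  pos <- c(.leaf_cols)
  for (cl in pos) if (any(obs[[cl]] <= 0))
    stop("non-positive sensor reading in ", cl, call. = FALSE)
  if (check_nbi) {
    for (i in 1:5) {
      nbi <- obs[[paste0("chl_l", i)]] / obs[[paste0("flav_l", i)]]
      if (any(abs(nbi - obs[[paste0("nbi_l", i)]]) > 1e-9 * pmax(abs(nbi), 1)))
        stop("nbi_l", i, " is not chl/flav within 1e-9 relative",
             call. = FALSE)
    }
  }
  if (!all(obs$leaf5_imputed %in% c(0, 1)))
    stop("leaf5_imputed must be 0/1", call. = FALSE)
  invisible(obs)
}

#' Assemble the 18-column feature table
#'
#' Builds the model input matrix from a plot-observation table: per-leaf
#' Chl, Flav and NBI for positions 1-5 plus the across-leaf mean of each
#' channel, 18 columns in the fixed order of [feature_names].
#'
#' @param obs validated plot observations.
#' @return data.table with 18 numeric columns named as [feature_names].
#' @export
feature_table <- function(obs) {
  obs <- validate_observations(obs)
  ft <- data.table::data.table(
    Chl_L1 = obs$chl_l1, Chl_L2 = obs$chl_l2, Chl_L3 = obs$chl_l3,
    Chl_L4 = obs$chl_l4, Chl_L5 = obs$chl_l5
  )
  ft[, "Chl_mean" := rowMeans(.SD), .SDcols = paste0("Chl_L", 1:5)]
  for (i in 1:5) data.table::set(ft, j = paste0("Flav_L", i),
                                 value = obs[[paste0("flav_l", i)]])
  ft[, "Flav_mean" := rowMeans(.SD), .SDcols = paste0("Flav_L", 1:5)]
  for (i in 1:5) data.table::set(ft, j = paste0("NBI_L", i),
                                 value = obs[[paste0("nbi_l", i)]])
  ft[, "NBI_mean" := rowMeans(.SD), .SDcols = paste0("NBI_L", 1:5)]
  data.table::setcolorder(ft, feature_names)
  ft[]
}

#' The four model input variable combinations
#'
#' Combination 1: the six Chl columns (leaves 1-5 and their mean);
#' combination 2: the six Flav columns; combination 3: the six NBI
#' columns; combination 4: all 18 variables.
#'
#' @param table a full 18-column feature table from [feature_table()].
#' @return named list of four data.tables (`Chl`, `Flav`, `NBI`, `All`).
#' @export
build_feature_combinations <- function(table) {
  missing <- setdiff(feature_names, names(table))
  if (length(missing))
    stop("schema error: feature table lacks ",
         paste(missing, collapse = ", "), call. = FALSE)
  table <- data.table::as.data.table(table)
  cols <- function(ch) c(paste0(ch, "_L", 1:5), paste0(ch, "_mean"))
  list(
    Chl  = table[, cols("Chl"), with = FALSE],
    Flav = table[, cols("Flav"), with = FALSE],
    NBI  = table[, cols("NBI"), with = FALSE],
    All  = table[, feature_names, with = FALSE]
  )
}

#' Read / write a plot-observation dataset
#'
#' Plain CSV with the documented header (identifier columns, 15 leaf
#' columns, `leaf5_imputed` flag), UTF-8, '.' decimal separator.  An
#' `anth`-prefixed column, if present on input, is accepted and dropped
#' (the anthocyanin channel is not analysed).  Writing then reading
#' reproduces all fields to full double precision.
#'
#' @param path CSV file path.
#' @return `read_dataset`: a validated data.table of observations.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obs <- data.table::fread(path, colClasses = list(
    character = c("site", "variety", "subspecies", "stage")))
  drop <- grep("^anth", names(obs), value = TRUE)
  if (length(drop)) obs[, (drop) := NULL]
  missing <- setdiff(.dataset_cols, names(obs))
  if (length(missing))
    stop("parse error: missing columns ", paste(missing, collapse = ", "),
         call. = FALSE)
  data.table::setcolorder(obs, .dataset_cols)
  validate_observations(obs)
  obs[]
}

#' @param observations a plot-observation table.
#' @rdname read_dataset
#' @export
write_dataset <- function(observations, path) {
  obs <- validate_observations(observations)
  data.table::setcolorder(obs, .dataset_cols)
  data.table::fwrite(obs, path)
  invisible(path)
}
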