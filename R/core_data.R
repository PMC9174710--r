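#' hilltopdyn: hilltopping-mediated spatial population dynamics
#'
#' Landscape connectivity indices routed through hilltop mating aggregations,
#' hierarchical Bayesian models of hilltop moth counts and annual caterpillar
#' censuses, WAIC model comparison, and a stochastic metapopulation simulator
#' contrasting random with hilltop-routed dispersal.
#'
#' @importFrom stats dnorm dpois rnorm rpois rlnorm runif var sd cor
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Landscape
# ---------------------------------------------------------------------------

#' Construct a landscape of larval patches and hilltop lek sites
#'
#' A landscape holds patch and hilltop coordinates (projected metres), hilltop
#' elevations (metres), and the derived patch-patch and patch-hilltop
#' Euclidean distance matrices in kilometres. All connectivity indices are
#' distance-decay kernel sums over these matrices.
#'
#' @param patches data.frame with columns `patch_id`, `x`, `y` (metres).
#' @param hilltops data.frame with columns `hilltop_id`, `x`, `y`,
#'   `elevation_m`.
#' @return An object of class `landscape`: list with `patches`, `hilltops`,
#'   `d_pp` (patch x patch, km), `d_ph` (patch x hilltop, km).
#' @export
landscape <- function(patches, hilltops) {
  need_p <- c("patch_id", "x", "y")
  need_h <- c("hilltop_id", "x", "y", "elevation_m")
  miss <- setdiff(need_p, names(patches))
  if (length(miss) > 0L)
    stop("patches is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_h, names(hilltops))
  if (length(miss) > 0L)
    stop("hilltops is missing column(s): ", paste(miss, collapse = ", "))
  pid <- as.character(patches$patch_id)
  hid <- as.character(hilltops$hilltop_id)
  if (anyDuplicated(pid))
    stop("duplicate patch_id: ", pid[duplicated(pid)][1L])
  if (anyDuplicated(hid))
    stop("duplicate hilltop_id: ", hid[duplicated(hid)][1L])
  if (!all(is.finite(patches$x)) || !all(is.finite(patches$y)))
    stop("patch coordinates must be finite")
  if (!all(is.finite(hilltops$x)) || !all(is.finite(hilltops$y)) ||
      !all(is.finite(hilltops$elevation_m)))
    stop("hilltop coordinates and elevations must be finite")

  pxy <- cbind(patches$x, patches$y)
  hxy <- cbind(hilltops$x, hilltops$y)
  d_pp <- as.matrix(stats::dist(pxy)) / 1000
  dimnames(d_pp) <- list(pid, pid)
  # cross distances, metres -> km
  d_ph <- sqrt(outer(pxy[, 1], hxy[, 1], "-")^2 +
               outer(pxy[, 2], hxy[, 2], "-")^2) / 1000
  dimnames(d_ph) <- list(pid, hid)
  validate_distances(d_pp, d_ph)

  structure(list(
    patches  = data.frame(patch_id = pid, x = patches$x, y = patches$y),
    hilltops = data.frame(hilltop_id = hid, x = hilltops$x, y = hilltops$y,
                          elevation_m = hilltops$elevation_m),
    d_pp = d_pp, d_ph = d_ph
  ), class = "landscape")
}

validate_distances <- function(d_pp, d_ph) {
  if (any(d_pp < 0) || any(d_ph < 0)) stop("distances must be nonnegative")
  if (any(abs(diag(d_pp)) > 1e-12)) stop("d_pp diagonal must be zero")
  if (any(abs(d_pp - t(d_pp)) > 1e-9)) stop("d_pp must be symmetric")
  invisible(TRUE)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d patches, %d hilltops\n",
              nrow(x$patches), nrow(x$hilltops)))
  invisible(x)
}

#' Read a landscape from two CSV files
#'
#' @param patches_path CSV with header `patch_id,x,y` (projected metres).
#' @param hilltops_path CSV with header `hilltop_id,x,y,elevation_m`.
#' @return A [landscape()] object; row order follows file order.
#' @export
read_landscape <- function(patches_path, hilltops_path) {
  landscape(read.csv(patches_path, stringsAsFactors = FALSE),
            read.csv(hilltops_path, stringsAsFactors = FALSE))
}

#' Write a landscape back to the two-file CSV format
#' @param land a [landscape()] object
#' @param patches_path,hilltops_path destination paths
#' @export
write_landscape <- function(land, patches_path, hilltops_path) {
  write.csv(land$patches, patches_path, row.names = FALSE, quote = FALSE)
  write.csv(land$hilltops, hilltops_path, row.names = FALSE, quote = FALSE)
  invisible(land)
}

# ---------------------------------------------------------------------------
# Panels: census, climate, moth counts
# ---------------------------------------------------------------------------

# years must be strictly increasing and contiguous; readers repair gaps by
# inserting all-missing years so lag bookkeeping downstream stays simple.
full_year_range <- function(years) seq(min(years), max(years))

#' Construct a census panel of mean caterpillar counts per bush
#'
#' @param mean_count patch x year matrix of mean caterpillars per bush
#'   (nonnegative; NA allowed). Rownames are patch ids, colnames years.
#' @param n_bushes patch x year matrix of positive integer sampling effort.
#' @return Object of class `census_panel` with `patch_ids`, `years`,
#'   `mean_count`, `n_bushes`.
#' @export
census_panel <- function(mean_count, n_bushes) {
  stopifnot(is.matrix(mean_count), is.matrix(n_bushes),
            all(dim(mean_count) == dim(n_bushes)))
  years <- as.integer(colnames(mean_count))
  if (any(diff(years) != 1L))
    stop("census years must be strictly increasing and contiguous")
  if (any(mean_count < 0, na.rm = TRUE))
    stop("mean_count must be nonnegative")
  if (any(!is.na(n_bushes) & (n_bushes <= 0 | n_bushes != round(n_bushes))))
    stop("n_bushes must be positive integers")
  structure(list(patch_ids = rownames(mean_count), years = years,
                 mean_count = mean_count, n_bushes = n_bushes),
            class = "census_panel")
}

#' @export
print.census_panel <- function(x, ...) {
  cat(sprintf("census_panel: %d patches x %d years (%d-%d)\n",
              length(x$patch_ids), length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Read a long-format census CSV (`patch_id,year,mean_count,n_bushes`)
#'
#' Absent (patch, year) rows become missing cells; gap years are inserted as
#' all-missing columns so the panel is contiguous.
#' @param path CSV path
#' @return a [census_panel()]
#' @export
read_census <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "year", "mean_count", "n_bushes")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("census file missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$mean_count < 0, na.rm = TRUE))
    stop("negative mean_count in census file")
  pids <- unique(as.character(df$patch_id))
  yrs <- full_year_range(df$year)
  mk <- function(col) {
    m <- matrix(NA_real_, length(pids), length(yrs),
                dimnames = list(pids, yrs))
    m[cbind(match(as.character(df$patch_id), pids),
            match(df$year, yrs))] <- df[[col]]
    m
  }
  census_panel(mk("mean_count"), mk("n_bushes"))
}

#' Write a census panel as a long-format CSV
#' @param panel a [census_panel()]
#' @param path destination
#' @export
write_census <- function(panel, path) {
  df <- expand.grid(patch_id = panel$patch_ids, year = panel$years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean_count <- as.vector(panel$mean_count)
  df$n_bushes <- as.vector(panel$n_bushes)
  df <- df[!is.na(df$mean_count), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' Construct an annual climate series
#'
#' Precipitation is the total over the previous precipitation year (mm);
#' temperature the mean over the previous dry season (deg C). Both are the
#' covariates entering the time-series model at lag one.
#'
#' @param years ordered integer years
#' @param precip_mm nonnegative totals
#' @param temp_c mean temperatures
#' @return object of class `climate_series`
#' @export
climate_series <- function(years, precip_mm, temp_c) {
  stopifnot(length(years) == length(precip_mm),
            length(years) == length(temp_c))
  if (any(precip_mm < 0, na.rm = TRUE)) stop("precip_mm must be nonnegative")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be increasing")
  structure(list(years = as.integer(years), precip = as.numeric(precip_mm),
                 temp = as.numeric(temp_c)), class = "climate_series")
}

#' Read a climate CSV (`year,precip_mm,temp_c`)
#' @param path CSV path
#' @return a [climate_series()]
#' @export
read_climate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "precip_mm", "temp_c")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("climate file missing column(s): ", paste(miss, collapse = ", "))
  climate_series(df$year, df$precip_mm, df$temp_c)
}

#' Write a climate series as CSV
#' @param clim a [climate_series()]
#' @param path destination
#' @export
write_climate <- function(clim, path) {
  write.csv(data.frame(year = clim$years, precip_mm = clim$precip,
                       temp_c = clim$temp),
            path, row.names = FALSE, quote = FALSE)
  invisible(clim)
}

#' Construct a panel of adult moth counts on hilltops
#'
#' Whole unsurveyed years are common (adult surveys are only practical in
#' high-abundance years); missing cells are dropped from model likelihoods,
#' never imputed.
#'
#' @param count hilltop x year matrix of nonnegative integer counts, NA where
#'   unsurveyed. Rownames hilltop ids, colnames years.
#' @return object of class `moth_panel`
#' @export
moth_panel <- function(count) {
  stopifnot(is.matrix(count))
  ok <- is.na(count) | (count >= 0 & count == round(count))
  if (!all(ok)) stop("moth counts must be nonnegative integers")
  structure(list(hilltop_ids = rownames(count),
                 years = as.integer(colnames(count)), count = count),
            class = "moth_panel")
}

#' Read a long-format moth-count CSV (`hilltop_id,year,count`)
#' @param path CSV path
#' @return a [moth_panel()]
#' @export
read_moths <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hilltop_id", "year", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("moth file missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$count < 0, na.rm = TRUE)) stop("negative moth count")
  if (any(df$count != round(df$count), na.rm = TRUE))
    stop("non-integer moth count")
  hids <- unique(as.character(df$hilltop_id))
  yrs <- full_year_range(df$year)
  m <- matrix(NA_real_, length(hids), length(yrs),
              dimnames = list(hids, yrs))
  m[cbind(match(as.character(df$hilltop_id), hids),
          match(df$year, yrs))] <- df$count
  moth_panel(m)
}

#' Write a moth panel as a long-format CSV
#' @param panel a [moth_panel()]
#' @param path destination
#' @export
write_moths <- function(panel, path) {
  df <- expand.grid(hilltop_id = panel$hilltop_ids, year = panel$years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- as.vector(panel$count)
  df <- df[!is.na(df$count), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

# ---------------------------------------------------------------------------
# Transforms
# ---------------------------------------------------------------------------

#' Offset-logged abundance matrix
#'
#' Counts include true zeros (local extinctions are part of the dynamics), so
#' every log-abundance in the package is ln(x + offset) with a default offset
#' of 1.
#'
#' @param panel a [census_panel()]
#' @param log_offset nonnegative constant added before the log (default 1)
#' @return patch x year matrix of ln(mean_count + log_offset); NA preserved
#' @export
log_abundance <- function(panel, log_offset = 1) {
  if (log_offset < 0) stop("log_offset must be nonnegative")
  if (log_offset == 0 && any(panel$mean_count == 0, na.rm = TRUE))
    stop("zero counts require log_offset > 0")
  log(panel$mean_count + log_offset)
}

#' Fit a z-score scaler with frozen statistics
#'
#' Scalers record the mean and sample standard deviation (denominator n-1)
#' used to standardize a covariate, plus whether values are logged (with
#' which offset) first. Freezing them lets the simulator reuse the
#' normalization of the observed data.
#'
#' @param values finite numeric values (NA dropped); at least two distinct
#' @param log take ln(v + log_offset) before standardizing?
#' @param log_offset offset for the log
#' @return object of class `scaler`: list(mean, sd, log, log_offset)
#' @export
fit_scaler <- function(values, log = FALSE, log_offset = 1) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values to fit a scaler")
  if (log) v <- log(v + log_offset)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("cannot fit scaler: values have zero variance")
  structure(list(mean = mean(v), sd = s, log = log, log_offset = log_offset),
            class = "scaler")
}

#' Apply a fitted scaler
#' @param values numeric values on the original scale
#' @param scaler a [fit_scaler()] result
#' @return standardized values, shape preserved
#' @export
apply_scaler <- function(values, scaler) {
  v <- values
  if (scaler$log) v <- log(v + scaler$log_offset)
  (v - scaler$mean) / scaler$sd
}

#' Invert a scaler (undo standardization and any log)
#' @param scaled standardized values
#' @param scaler a [fit_scaler()] result
#' @return values on the original scale
#' @export
invert_scaler <- function(scaled, scaler) {
  v <- scaled * scaler$sd + scaler$mean
  if (scaler$log) v <- exp(v) - scaler$log_offset
  v
}

#' An identity scaler (mean 0, sd 1, no log)
#' @return a `scaler` that leaves values unchanged
#' @export
identity_scaler <- function() {
  structure(list(mean = 0, sd = 1, log = FALSE, log_offset = 0),
            class = "scaler")
}
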