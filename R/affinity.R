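GAS_CONSTANT <- 8.3145      # J / (K mol)

#' Convert a binding free energy to an inhibition constant
#'
#' Ki = exp(dG / RT) with dG in kJ/mol, R = 8.3145 J/(K mol) and
#' T = 298.15 K by default. Favorable binding (dG < 0) gives Ki < 1.
#'
#' @param dg binding free energy in kJ/mol
#' @param T temperature in K
#' @return dimensionless Ki
#' @export
ki_from_dg <- function(dg, T = 298.15) {
  if (T <= 0) stop("ki_from_dg: temperature must be > 0")
  exp(dg * 1000 / (GAS_CONSTANT * T))
}

#' @rdname ki_from_dg
#' @param ki dimensionless inhibition constant (> 0)
#' @return binding free energy in kJ/mol
#' @export
dg_from_ki <- function(ki, T = 298.15) {
  if (T <= 0) stop("dg_from_ki: temperature must be > 0")
  if (any(ki <= 0)) stop("dg_from_ki: Ki must be > 0")
  log(ki) * GAS_CONSTANT * T / 1000
}

#' Load or build an affinity table
#'
#' Either reads a CSV (columns name, ki_pred, ki_exp, optional dg_kJmol)
#' or loads the packaged fixture by name. The \code{"table3"} fixture
#' holds the five channel blockers (amantadine, TEA, rimantadine,
#' sotalol, bretylium tosylate) with docking-predicted and experimental
#' dimensionless Ki values.
#'
#' @param source CSV path or fixture name ("table3")
#' @return object of class \code{affinity_table} (a data.frame)
#' @export
affinity_table <- function(source = "table3") {
  path <- if (file.exists(source)) source
          else system.file("extdata", paste0(source, ".csv"),
                           package = "poremd")
  if (!nzchar(path) || !file.exists(path))
    stop("affinity_table: no such file or fixture: ", source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "ki_pred", "ki_exp") %in% names(df)))
    stop("affinity_table: need columns name, ki_pred, ki_exp")
  if (anyDuplicated(df$name)) stop("affinity_table: duplicate names")
  ok <- is.na(df$ki_pred) | df$ki_pred > 0
  ok <- ok & (is.na(df$ki_exp) | df$ki_exp > 0)
  if (!all(ok)) stop("affinity_table: Ki values must be > 0")
  class(df) <- c("affinity_table", "data.frame")
  df
}

#' Predicted-versus-experimental affinity correlation
#'
#' Pearson correlation between predicted and experimental Ki over the
#' complete records, after log10 transform by default (equivalently, the
#' correlation of the binding free energies, since log Ki is affine in
#' dG).
#'
#' @param table an \code{affinity_table}
#' @param scale "log" (default) or "linear"
#' @return Pearson correlation coefficient
#' @export
affinity_correlation <- function(table, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  cc <- stats::complete.cases(table$ki_pred, table$ki_exp)
  if (sum(cc) < 3)
    stop("affinity_correlation: need >= 3 complete records")
  x <- table$ki_pred[cc]; y <- table$ki_exp[cc]
  if (scale == "log") { x <- log10(x); y <- log10(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("affinity_correlation: zero variance (undefined correlation)")
  stats::cor(x, y)
}
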