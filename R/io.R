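#' Parse a run configuration
#'
#' Reads a flat YAML or JSON configuration (keys named after the model symbols:
#' `mu_c`, `omega`, `b_real`, `b_imag`, `tau`, `gamma`, `alpha`; forcing blocks
#' `additive` and `parametric` with `variant`, `F`, `omega_prime`, `t_start`,
#' `t_stop`, `mu_p`; an `integration` block with `z0_real`, `z0_imag`, `mu0`,
#' `rtol`, `atol`, `dt_out`, `hold_mu`; and `t_span`), validates it, fills
#' every omitted key with the documented default, and rejects unknown keys.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL`.
#' @param overrides Named list applied on top of the file contents (same keys).
#' @return A list with validated components `params`, `additive`, `parametric`,
#'   `config`, `t_span`, carrying class `hopf_runconfig`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  raw <- utils::modifyList(raw, overrides)

  known_top <- c("mu_c", "omega", "b_real", "b_imag", "tau", "gamma", "alpha",
                 "additive", "parametric", "integration", "t_span")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  pargs <- raw[intersect(names(raw),
                         c("mu_c", "omega", "b_real", "b_imag",
                           "tau", "gamma", "alpha"))]
  params <- do.call(hopf_params, pargs)

  ab <- raw$additive %||% list()
  unknown <- setdiff(names(ab), c("variant", "F", "omega_prime",
                                  "t_start", "t_stop"))
  if (length(unknown))
    stop("unknown additive-forcing key(s): ", paste(unknown, collapse = ", "))
  additive <- do.call(additive_forcing,
                      c(list(variant = ab$variant %||% "none"),
                        ab[setdiff(names(ab), "variant")]))

  pb <- raw$parametric %||% list()
  unknown <- setdiff(names(pb), c("variant", "mu_p", "t_start", "t_stop"))
  if (length(unknown))
    stop("unknown parametric-forcing key(s): ", paste(unknown, collapse = ", "))
  parametric <- do.call(parametric_forcing,
                        c(list(variant = pb$variant %||% "none",
                               mu_c = params$mu_c),
                          pb[setdiff(names(pb), "variant")]))

  ib <- raw$integration %||% list()
  unknown <- setdiff(names(ib), c("z0_real", "z0_imag", "mu0", "rtol", "atol",
                                  "dt_out", "hold_mu", "method"))
  if (length(unknown))
    stop("unknown integration key(s): ", paste(unknown, collapse = ", "))
  config <- integration_config(
    z0 = complex(real = ib$z0_real %||% 0.01, imaginary = ib$z0_imag %||% 0),
    mu0 = ib$mu0, rtol = ib$rtol %||% 1e-8, atol = ib$atol %||% 1e-10,
    dt_out = ib$dt_out, hold_mu = ib$hold_mu %||% FALSE,
    method = ib$method %||% "lsoda")

  t_span <- as.numeric(raw$t_span %||% c(0, 100))
  if (length(t_span) != 2L || !(t_span[1] < t_span[2]))
    stop("'t_span' must be two increasing numbers")

  structure(list(params = params, additive = additive, parametric = parametric,
                 config = config, t_span = t_span),
            class = "hopf_runconfig")
}

# flat provenance list for sidecar JSON
.provenance <- function(trace) {
  p <- attr(trace, "params"); a <- attr(trace, "additive")
  q <- attr(trace, "parametric"); cfg <- attr(trace, "config")
  drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
  list(package = "hopfbundle",
       version = as.character(utils::packageVersion("hopfbundle")),
       params = unclass(p),
       additive = drop_null(unclass(a)),
       parametric = drop_null(unclass(q)),
       integration = list(z0_real = Re(cfg$z0), z0_imag = Im(cfg$z0),
                          mu0 = cfg$mu0 %||% (-p$alpha * p$tau / 2),
                          rtol = cfg$rtol, atol = cfg$atol,
                          dt_out = attr(trace, "dt_out"),
                          hold_mu = cfg$hold_mu, method = cfg$method),
       t_span = c(trace$t[1], trace$t[nrow(trace)]))
}

#' Write a trace to CSV with a provenance sidecar
#'
#' Writes the sample table as CSV (`t,x,y,mu`) and, alongside it, a JSON file
#' (`<path>.json`) holding the full provenance: model parameters, forcing
#' protocols, solver settings and package version, enough to re-run the
#' simulation bit-identically.
#'
#' @param trace A `hopf_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hopf_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(.provenance(trace), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace CSV
#'
#' Accepts the native format (`t,x,y,mu`) or a plain two-column time/position
#' table.  Single-channel traces (no `y`) support only amplitude-envelope and
#' spectral statistics, not phase-based ones.
#'
#' @param path CSV path.
#' @return A data frame; class `hopf_trace` when all native columns are
#'   present (provenance attributes restored from the sidecar JSON if found).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) == 2L) names(df) <- c("t", "x")
  if (is.unsorted(df$t, strictly = TRUE))
    stop("trace time stamps must be strictly increasing")
  side <- paste0(path, ".json")
  if (all(c("t", "x", "y", "mu") %in% names(df))) {
    attrs <- NULL
    if (file.exists(side)) {
      pv <- jsonlite::read_json(side, simplifyVector = TRUE)
      attrs <- pv
      attr(df, "params") <- do.call(hopf_params, pv$params)
      attr(df, "dt_out") <- pv$integration$dt_out
    }
    class(df) <- c("hopf_trace", "data.frame")
  }
  df
}
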