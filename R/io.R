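#' Read a calcium trace from CSV
#'
#' Expects a header `time_ms,ca_uM` and a strictly increasing uniform time
#' grid; parse problems are reported with the offending row number.
#'
#' @param path CSV file path.
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df)[1:2], c("time_ms", "ca_uM")))
    stop(sprintf("'%s': expected header 'time_ms,ca_uM'", path))
  tm <- suppressWarnings(as.numeric(df$time_ms))
  ca <- suppressWarnings(as.numeric(df$ca_uM))
  bad <- which(is.na(tm) | is.na(ca))
  if (length(bad))
    stop(sprintf("'%s': non-numeric cell at data row %d", path, bad[1L]))
  if (length(tm) > 1L) {
    d <- diff(tm)
    if (any(d <= 0))
      stop(sprintf("'%s': time not strictly increasing at data row %d",
                   path, which(d <= 0)[1L] + 1L))
    rel <- abs(d - d[1L]) / d[1L]
    if (any(rel > 1e-6))
      stop(sprintf("'%s': non-uniform time grid at data row %d",
                   path, which(rel > 1e-6)[1L] + 1L))
    dt <- d[1L]
  } else dt <- 1
  ca_trace(ca, dt = dt, t0 = tm[1L])
}

#' Write a calcium trace to CSV
#'
#' Full-precision, locale-independent serialization; [read_ca_trace()]
#' round-trips the values bitwise.
#'
#' @param trace A [ca_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  tt <- ca_trace_times(trace)
  lines <- c("time_ms,ca_uM",
             sprintf("%.17g,%.17g", tt, trace$values))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spike train from plain text
#'
#' One spike time (ms) per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Numeric vector of strictly increasing spike times.
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sp <- suppressWarnings(as.numeric(lines))
  if (anyNA(sp)) stop(sprintf("'%s': non-numeric spike time", path))
  validate_spike_train(sp)
  sp
}

#' Write a spike train to plain text
#' @param spikes Spike times, ms.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(spikes, path) {
  validate_spike_train(spikes)
  writeLines(sprintf("%.17g", spikes), path)
  invisible(path)
}

#' Write release events to CSV
#' @param events Event data frame from [sample_release_events()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.builtin_param_path <- function(name) {
  f <- system.file("extdata", paste0(name, ".json"), package = "synrelease")
  if (!nzchar(f)) stop(sprintf("unknown built-in parameter set '%s'", name))
  f
}

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
}

#' Load a parameter bundle from JSON
#'
#' Reads sensor kinetics, release models, facilitation metaparameters and/or
#' a calcium transient spec from structured text.  Built-in names:
#' `"table1"` (sensor kinetics, published units, converted to uM/ms on
#' load), `"table2_400nm"` (release models fitted 400 nm from a 100-channel
#' cluster), `"table3"` (facilitation metaparameters) and `"default"` (all
#' of them).  Unknown keys are rejected; every loaded object is validated by
#' its constructor, and facilitation labels are checked against the release
#' components.
#'
#' @param name_or_path A built-in name or a path to a JSON file.
#' @return A list of class `parameter_bundle` with any of the elements
#'   `sensors`, `release_models`, `facilitation`, `calcium`.
#' @export
load_parameters <- function(name_or_path = "default") {
  path <- if (file.exists(name_or_path)) name_or_path
          else .builtin_param_path(name_or_path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  .check_keys(raw, c("sensors", "release_models", "facilitation", "calcium"),
              basename(path))
  out <- list()
  errs <- character(0)
  grab <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      errs <<- c(errs, sprintf("%s: %s", what, conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(raw$sensors)) {
    out$sensors <- lapply(names(raw$sensors), function(nm) {
      s <- raw$sensors[[nm]]
      .check_keys(s, c("n_sites", "k_on_per_M_s", "k_off_per_s",
                       "gamma_per_s", "coop_b", "refractory_eps_ms"),
                  paste0("sensors$", nm))
      grab(sensor_kinetics(s$n_sites,
                           k_on = s$k_on_per_M_s * 1e-9,
                           k_off = s$k_off_per_s * 1e-3,
                           coop_b = s$coop_b,
                           gamma_fuse = s$gamma_per_s * 1e-3,
                           refractory_eps = if (is.null(s$refractory_eps_ms)) 0
                                            else s$refractory_eps_ms,
                           label = nm),
           paste0("sensors$", nm))
    })
    names(out$sensors) <- names(raw$sensors)
  }
  if (!is.null(raw$release_models)) {
    out$release_models <- lapply(names(raw$release_models), function(nm) {
      m <- raw$release_models[[nm]]
      .check_keys(m, c("r0_per_ms", "components"), paste0("release_models$", nm))
      comps <- lapply(m$components, function(cc) {
        .check_keys(cc, c("label", "P", "tau_ms", "k_per_ms", "mu_ms",
                          "sigma_ms"), paste0("release_models$", nm))
        grab(release_component(cc$P, cc$tau_ms, cc$k_per_ms, cc$mu_ms,
                               cc$sigma_ms),
             paste0("release_models$", nm, "$", cc$label))
      })
      names(comps) <- vapply(m$components, `[[`, "", "label")
      grab(release_model(m$r0_per_ms, comps, nm), paste0("release_models$", nm))
    })
    names(out$release_models) <- names(raw$release_models)
  }
  if (!is.null(raw$facilitation)) {
    out$facilitation <- lapply(names(raw$facilitation), function(nm) {
      lapply(raw$facilitation[[nm]], function(fc) {
        .check_keys(fc, c("label", "tau_ms", "n_steps", "xi"),
                    paste0("facilitation$", nm))
        grab(facil_component(fc$tau_ms, fc$n_steps, fc$xi),
             paste0("facilitation$", nm))
      })
    })
    names(out$facilitation) <- names(raw$facilitation)
  }
  if (!is.null(raw$calcium)) {
    ca <- raw$calcium
    .check_keys(ca, c("baseline_uM", "onset_delay_ms", "distance_um",
                      "length_constant_um", "components"), "calcium")
    comps <- do.call(rbind, lapply(ca$components, function(x)
      c(amplitude = x$amplitude_uM, tau = x$tau_ms)))
    out$calcium <- grab(ca_transient_spec(comps, baseline = ca$baseline_uM,
                                          onset_delay = ca$onset_delay_ms,
                                          distance = ca$distance_um,
                                          length_constant = ca$length_constant_um),
                        "calcium")
  }
  if (length(errs))
    stop("parameter validation failed:\n  ", paste(errs, collapse = "\n  "))
  # cross-reference facilitation labels against release components
  if (!is.null(out$facilitation) && !is.null(out$release_models)) {
    comp_labels <- unlist(lapply(out$release_models, function(m)
      names(m$components)))
    bad <- setdiff(names(out$facilitation), comp_labels)
    if (length(bad))
      stop("facilitation refers to unknown release component(s): ",
           paste(bad, collapse = ", "))
  }
  structure(out, class = "parameter_bundle")
}
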