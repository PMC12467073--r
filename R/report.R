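#' Regenerate and check the reference energy tables
#'
#' Recomputes the tissue/muscle benchmark table ([reference_rows()]) and
#' the nanoparticle size-speed table ([np_scenarios()]) from the force
#' laws, writes them as `table2.csv` and `table3.csv`, and diffs every
#' numeric energy cell against the published reference values at the
#' precision those values are printed with.
#'
#' @param dir Output directory (created if missing).
#' @param n Trace grid size for the numerical columns of the
#'   nanoparticle table.
#' @param quiet Suppress the per-scenario log lines.
#' @return Invisibly, a list with elements `table2`, `table3` (the
#'   computed tibbles), `diffs` (one row per checked cell: computed,
#'   reference, relative error, pass) and `all_match` (logical).
#' @examples
#' res <- reproduce_tables(tempdir(), quiet = TRUE)
#' res$all_match
#' @export
reproduce_tables <- function(dir = ".", n = 10001L, quiet = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  t2 <- reference_rows()
  t3 <- np_scenarios(n = n)

  table2_out <- tibble::tibble(
    Case = t2$case, Parameters = t2$parameters, Loading = t2$loading,
    W_el_J = t2$w_el, W_visc_J = t2$w_visc, W_total_J = t2$w_total)
  table3_out <- tibble::tibble(
    Case = t3$label, D_nm = t3$diameter_nm, k_N_per_m = t3$k,
    eta_Ns_per_m = t3$eta, T_s = t3$T_s,
    W_el_J = t3$w_el, W_visc_J = t3$w_visc)
  readr::write_csv(table2_out, file.path(dir, "table2.csv"))
  readr::write_csv(table3_out, file.path(dir, "table3.csv"))

  ref <- golden_reference()
  computed <- c(
    t2$w_el[1:3], t2$w_visc[1:3], t2$w_total[1:3], t2$w_total[4:5],
    t3$w_el, t3$w_visc)
  diffs <- tibble::tibble(
    cell = ref$cell, computed = computed, reference = ref$value)
  diffs$rel_err <- ifelse(diffs$reference == 0, abs(diffs$computed),
                          abs(diffs$computed / diffs$reference - 1))
  diffs$pass <- diffs$rel_err < 1e-4
  if (!quiet) {
    for (i in seq_len(nrow(t3))) {
      message(sprintf("%-20s  numerical  W_el=%.6g J  W_visc=%.6g J  W_total=%.6g J",
                      t3$label[i], t3$w_el_num[i], t3$w_visc_num[i],
                      t3$w_total_num[i]))
    }
    bad <- diffs[!diffs$pass, ]
    if (nrow(bad) > 0) {
      message("MISMATCHED CELLS:")
      for (i in seq_len(nrow(bad))) {
        message(sprintf("  %-28s computed %.6g vs reference %.6g",
                        bad$cell[i], bad$computed[i], bad$reference[i]))
      }
    }
  }
  invisible(list(table2 = table2_out, table3 = table3_out,
                 diffs = diffs, all_match = all(diffs$pass)))
}

# published energy cells the regenerated tables are diffed against
golden_reference <- function() {
  tibble::tibble(
    cell = c("t2 hookean W_el", "t2 kv_slow W_el", "t2 kv_fast W_el",
             "t2 hookean W_visc", "t2 kv_slow W_visc", "t2 kv_fast W_visc",
             "t2 hookean W_total", "t2 kv_slow W_total", "t2 kv_fast W_total",
             "t2 hill_slow W", "t2 hill_fast W",
             "t3 small_slow W_el", "t3 small_fast W_el",
             "t3 large_slow W_el", "t3 large_fast W_el",
             "t3 small_slow W_visc", "t3 small_fast W_visc",
             "t3 large_slow W_visc", "t3 large_fast W_visc"),
    value = c(5.0, 5.0, 5.0,
              0.0, 0.50, 50.0,
              5.0, 5.50, 55.0,
              4.0833, 2.25,
              1.25e-17, 1.25e-17, 8.00e-16, 8.00e-16,
              1.25e-20, 1.25e-17, 8.00e-19, 8.00e-16))
}

#' Write / read a loading trace as CSV
#'
#' Traces are written RFC-4180 style with explicitly unit-suffixed
#' headers (`t_s, x_m, v_m_per_s, F_N, P_W, W_el_J, W_visc_J, W_adh_J,
#' W_total_J`) and shortest round-trip number formatting, so a written
#' trace re-reads value-identical.
#'
#' @param trace A `kv_trace` from [sample_trace()] / [partition_trace()].
#' @param path Output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the trace tibble (without the budget attribute — re-partition to
#'   recover it).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kv_trace"))
  # 17 significant digits in scientific notation: enough for any double to
  # re-read bit-identical
  sci <- function(x) sprintf("%.16e", x)
  out <- tibble::tibble(
    t_s = sci(trace$t), x_m = sci(trace$x), v_m_per_s = sci(trace$v),
    F_N = sci(trace$F), P_W = sci(trace$P), W_el_J = sci(trace$w_el),
    W_visc_J = sci(trace$w_visc), W_adh_J = sci(trace$w_adh),
    W_total_J = sci(trace$w_total))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  # parse with base strtod for exact (shortest-roundtrip) doubles
  raw <- tibble::as_tibble(lapply(raw, as.numeric))
  tibble::tibble(
    t = raw$t_s, x = raw$x_m, v = raw$v_m_per_s, F = raw$F_N, P = raw$P_W,
    w_el = raw$W_el_J, w_visc = raw$W_visc_J, w_adh = raw$W_adh_J,
    w_total = raw$W_total_J)
}

#' Serialize an energy budget to JSON
#'
#' @param budget An [energy_budget()].
#' @param path Optional output file; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
budget_json <- function(budget, path = NULL) {
  stopifnot(inherits(budget, "energy_budget"))
  obj <- list(w_el = budget$w_el, w_visc = budget$w_visc,
              w_adh = budget$w_adh, w_total = budget$w_total,
              units = "J", method = budget$method)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Emit every built-in scenario as a JSON parameter fixture
#'
#' Writes one JSON file per built-in scenario (five tissue/muscle
#' benchmark rows, four nanoparticle grid cells, two worked-example
#' entries) with explicit unit strings, so external tools can re-run any
#' scenario from its serialized parameters.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir = "fixtures") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, obj) {
    p <- file.path(dir, paste0(name, ".json"))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), p)
    paths <<- c(paths, p)
  }
  kv <- kv_params(1000, 50)
  emit("tissue_kv_slow", list(model = "kelvin_voigt", k = kv$k,
       k_units = "N/m", eta = kv$eta, eta_units = "N.s/m", D = 0.10,
       D_units = "m", T = 1.0, T_units = "s"))
  emit("tissue_kv_fast", list(model = "kelvin_voigt", k = kv$k,
       k_units = "N/m", eta = kv$eta, eta_units = "N.s/m", D = 0.10,
       D_units = "m", T = 0.01, T_units = "s"))
  emit("tissue_hookean", list(model = "hookean", k = kv$k,
       k_units = "N/m", D = 0.10, D_units = "m"))
  emit("muscle_hill_slow", list(model = "hill", fmax = 100,
       fmax_units = "N", a = 10, a_units = "N", b = 0.5,
       b_units = "m/s", D = 0.05, D_units = "m", v = 0.10,
       v_units = "m/s"))
  emit("muscle_hill_fast", list(model = "hill", fmax = 100,
       fmax_units = "N", a = 10, a_units = "N", b = 0.5,
       b_units = "m/s", D = 0.05, D_units = "m", v = 0.50,
       v_units = "m/s"))
  grid <- np_scenarios(n = 2L)
  for (i in seq_len(nrow(grid))) {
    nm <- tolower(gsub("[^a-z]+", "_", tolower(grid$label[i])))
    nm <- gsub("^_|_$", "", nm)
    emit(paste0("np_", nm), list(model = "kelvin_voigt",
         diameter = grid$diameter_nm[i], diameter_units = "nm",
         k = grid$k[i], k_units = "N/m", eta = grid$eta[i],
         eta_units = "N.s/m", D = grid$depth_m[i], D_units = "m",
         T = grid$T_s[i], T_units = "s"))
  }
  we <- worked_example_np(n = 2L)
  for (i in seq_len(nrow(we))) {
    nm <- if (we$T_s[i] > 1e-3) "slow" else "fast"
    emit(paste0("np_worked_example_", nm), list(model = "kelvin_voigt",
         k = we$k[i], k_units = "N/m", eta = we$eta[i],
         eta_units = "N.s/m", D = we$depth_m[i], D_units = "m",
         T = we$T_s[i], T_units = "s"))
  }
  invisible(paths)
}
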