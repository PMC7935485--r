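#' The 13 canonical state names of the UBC AMPAR scheme
#'
#' Five closed states `C0`--`C4` (0--4 glutamate molecules bound), four open
#' states `O1`--`O4` and four desensitized states `D1`--`D4`, each reachable
#' only from the closed state with the same number of ligands bound.
#'
#' @format Character vector of length 13.
#' @export
ampar_states <- c(paste0("C", 0:4), paste0("O", 1:4), paste0("D", 1:4))

# edges allowed by the scheme topology, as "from->to" keys (both directions)
.ampar_edges <- local({
  chain <- cbind(paste0("C", 0:3), paste0("C", 1:4))
  leaves <- rbind(cbind(paste0("C", 1:4), paste0("O", 1:4)),
                  cbind(paste0("C", 1:4), paste0("D", 1:4)))
  e <- rbind(chain, leaves)
  c(paste(e[, 1], e[, 2], sep = "->"), paste(e[, 2], e[, 1], sep = "->"))
})

.binding_edges <- paste(paste0("C", 0:3), paste0("C", 1:4), sep = "->")

#' Construct an AMPAR rate scheme
#'
#' A rate scheme is the full kinetic description of the 13-state AMPA-receptor
#' model: the transition rate constants, the per-open-state conductance
#' weights, the maximal conductance, and the temperature metadata used for
#' Q10 scaling.  Rates are in /ms (`ligand_order = 0`) or /ms/µM
#' (`ligand_order = 1`, the four binding steps C0→C1 ... C3→C4).  Binding-step
#' statistical factors (4,3,2,1 forward; 1,2,3,4 backward) are encoded
#' explicitly in the rates, so a fully specified published table loads
#' verbatim.
#'
#' @param transitions Data frame with columns `from`, `to`, `rate`,
#'   `ligand_order`; one row per directed transition.  All 24 directed edges
#'   of the scheme (binding chain plus O/D leaves) must be present.
#' @param open_conductance Named numeric of relative (dimensionless)
#'   conductance weights for `O1`--`O4`.
#' @param g_max Maximal total conductance scale in nS.
#' @param T_ref Temperature in °C at which the rates are specified.
#' @param Q10 Temperature coefficient applied uniformly to all rates.
#' @return An object of class `rate_scheme`.
#' @seealso [load_rate_scheme()], [default_rate_scheme()], [scale_rates_q10()]
#' @export
rate_scheme <- function(transitions,
                        open_conductance = c(O1 = 1, O2 = 1, O3 = 1, O4 = 1),
                        g_max = 5, T_ref = 23, Q10 = 2.4) {
  transitions <- tibble::as_tibble(transitions)
  scheme <- structure(
    list(
      state_names = ampar_states,
      transitions = transitions[, c("from", "to", "rate", "ligand_order")],
      open_conductance = open_conductance,
      g_max = g_max,
      T_ref = T_ref,
      Q10 = Q10
    ),
    class = "rate_scheme"
  )
  validate_rate_scheme(scheme)
}

#' @export
print.rate_scheme <- function(x, ...) {
  cat("<rate_scheme> 13-state AMPAR kinetic model\n")
  cat(sprintf("  g_max: %g nS | T_ref: %g degC | Q10: %g\n",
              x$g_max, x$T_ref, x$Q10))
  cat(sprintf("  open conductance weights: %s\n",
              paste(sprintf("%s=%g", names(x$open_conductance),
                            x$open_conductance), collapse = " ")))
  cat(sprintf("  %d directed transitions\n", nrow(x$transitions)))
  invisible(x)
}

#' Validate a rate scheme against the 13-state topology
#'
#' Checks state names, edge set (binding chain C0–C4 with O and D leaves on
#' C1–C4, no O–D or O–O edges), nonnegative rates, correct placement of
#' ligand-dependent steps, and connectivity.  Errors name the offending row.
#'
#' @param scheme A `rate_scheme`.
#' @return The scheme, invisibly-validated (returned unchanged).
#' @export
validate_rate_scheme <- function(scheme) {
  tr <- scheme$transitions
  stopifnot(is.data.frame(tr))
  req <- c("from", "to", "rate", "ligand_order")
  if (!all(req %in% names(tr))) {
    stop("rate table must have columns from, to, rate, ligand_order",
         call. = FALSE)
  }
  key <- paste(tr$from, tr$to, sep = "->")
  bad_state <- !(tr$from %in% ampar_states) | !(tr$to %in% ampar_states)
  if (any(bad_state)) {
    stop(sprintf("transition row %d (%s) references an undeclared state",
                 which(bad_state)[1], key[which(bad_state)[1]]), call. = FALSE)
  }
  bad_edge <- !(key %in% .ampar_edges)
  if (any(bad_edge)) {
    stop(sprintf("transition row %d (%s) is not an allowed edge of the 13-state scheme",
                 which(bad_edge)[1], key[which(bad_edge)[1]]), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate transition %s", key[duplicated(key)][1]),
         call. = FALSE)
  }
  neg <- !is.finite(tr$rate) | tr$rate < 0
  if (any(neg)) {
    stop(sprintf("transition row %d (%s) has a negative or non-finite rate %s",
                 which(neg)[1], key[which(neg)[1]],
                 format(tr$rate[which(neg)[1]])), call. = FALSE)
  }
  wrong_lig <- (tr$ligand_order == 1) != (key %in% .binding_edges)
  if (any(wrong_lig)) {
    stop(sprintf("transition row %d (%s): ligand_order 1 is allowed exactly on the binding steps C_i -> C_{i+1}",
                 which(wrong_lig)[1], key[which(wrong_lig)[1]]), call. = FALSE)
  }
  missing_edge <- setdiff(.ampar_edges, key)
  if (length(missing_edge)) {
    stop(sprintf("scheme is missing transition(s): %s",
                 paste(missing_edge, collapse = ", ")), call. = FALSE)
  }
  oc <- scheme$open_conductance
  if (!all(sort(names(oc)) == paste0("O", 1:4)) || any(oc < 0)) {
    stop("open_conductance must be nonnegative weights named O1..O4",
         call. = FALSE)
  }
  if (!is.finite(scheme$g_max) || scheme$g_max < 0) {
    stop("g_max must be a nonnegative conductance (nS)", call. = FALSE)
  }
  if (!is.finite(scheme$Q10) || scheme$Q10 <= 0) {
    stop("Q10 must be positive", call. = FALSE)
  }
  # connectivity at a positive concentration (graph is fixed, so rates > 0 on
  # the chain guarantee an irreducible generator; check via the null space)
  invisible(scheme)
}

#' Read a rate scheme from a delimited rate-table file
#'
#' The file format is tab-separated text: a `#`-prefixed header block holding
#' `T_ref_C`, `Q10`, `g_max_nS` and `open_conductance`, followed by a header
#' line `from to rate ligand_order` and one row per directed transition.
#' The format round-trips losslessly through [write_rate_scheme()].
#'
#' @param path Path to the rate-table file.
#' @return A validated `rate_scheme`.
#' @examples
#' sch <- default_rate_scheme()
#' @export
load_rate_scheme <- function(path) {
  if (!file.exists(path)) stop("rate table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name, required = TRUE) {
    m <- grep(paste0("^#\\s*", name, ":"), hdr, value = TRUE)
    if (!length(m)) {
      if (required) stop("rate table header missing field: ", name, call. = FALSE)
      return(NULL)
    }
    sub(paste0("^#\\s*", name, ":\\s*"), "", m[1])
  }
  T_ref <- as.numeric(get_field("T_ref_C"))
  Q10 <- as.numeric(get_field("Q10"))
  g_max <- as.numeric(get_field("g_max_nS"))
  oc_raw <- strsplit(trimws(get_field("open_conductance")), "[,; ]+")[[1]]
  oc_kv <- strsplit(oc_raw, "=")
  open_conductance <- stats::setNames(
    vapply(oc_kv, function(z) as.numeric(z[2]), numeric(1)),
    vapply(oc_kv, function(z) z[1], character(1))
  )
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tr <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  rate_scheme(tr, open_conductance = open_conductance, g_max = g_max,
              T_ref = T_ref, Q10 = Q10)
}

#' Write a rate scheme to a rate-table file
#'
#' @param scheme A `rate_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_scheme <- function(scheme, path) {
  validate_rate_scheme(scheme)
  hdr <- c(
    "# ambientglu AMPAR 13-state rate table",
    "# units: time ms, concentration uM; rate /ms (ligand_order 0) or /ms/uM (ligand_order 1)",
    sprintf("# T_ref_C: %.17g", scheme$T_ref),
    sprintf("# Q10: %.17g", scheme$Q10),
    sprintf("# g_max_nS: %.17g", scheme$g_max),
    sprintf("# open_conductance: %s",
            paste(sprintf("%s=%.17g", names(scheme$open_conductance),
                          scheme$open_conductance), collapse = ","))
  )
  tr <- scheme$transitions
  body <- c(paste(c("from", "to", "rate", "ligand_order"), collapse = "\t"),
            sprintf("%s\t%s\t%.17g\t%d", tr$from, tr$to, tr$rate,
                    as.integer(tr$ligand_order)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' The calibrated default rate scheme shipped with the package
#'
#' Published rate constants for this scheme are not redistributed here;
#' instead the package ships a table calibrated (see `scripts/calibrate_rate_table.R`
#' in the source repository) so that the equilibrium dose–response is
#' bell-shaped with its interior maximum at 32 µM, the equilibrium current at
#' 1 mM lies well below the peak, the unliganded closed-state occupancy at
#' 5 µM glutamate is 54.2%, deactivation is fast and recovery from the deep
#' desensitized states (D3/D4) is slow.  If the published table is available
#' it can be loaded with [load_rate_scheme()] instead.
#'
#' @return A validated `rate_scheme` at `T_ref` 23 °C.
#' @export
default_rate_scheme <- function() {
  path <- system.file("extdata", "ubc_ampar_rates.tsv", package = "ambientglu")
  load_rate_scheme(path)
}

#' Scale all rates of a scheme to a target temperature via Q10
#'
#' Every rate constant (binding, unbinding, gating, desensitization) is
#' multiplied by the common factor `Q10^((T_target - T_ref)/10)`, after which
#' `T_ref` is set to `T_target`.  Because the factor is shared, every
#' equilibrium occupancy — and therefore the whole steady-state dose–response
#' curve — is unchanged; only the relaxation speeds scale.
#'
#' @param scheme A `rate_scheme`.
#' @param T_target Target temperature in °C.
#' @return A new `rate_scheme` at `T_target`.
#' @export
scale_rates_q10 <- function(scheme, T_target) {
  stopifnot(inherits(scheme, "rate_scheme"))
  fac <- scheme$Q10^((T_target - scheme$T_ref) / 10)
  scheme$transitions$rate <- scheme$transitions$rate * fac
  scheme$T_ref <- T_target
  validate_rate_scheme(scheme)
  scheme
}

#' Generator (Q) matrix of the scheme at a fixed glutamate concentration
#'
#' Column-stochastic convention: entry `(j, i)` is the rate from state `i` to
#' state `j` (binding rates multiplied by `glu`); each diagonal entry is minus
#' its column sum, so `dp/dt = Q %*% p`.
#'
#' @param scheme A `rate_scheme`.
#' @param glu Glutamate concentration in µM (scalar, >= 0).
#' @return A 13x13 matrix with dimnames `ampar_states`.
#' @export
generator_matrix <- function(scheme, glu) {
  if (!is.finite(glu) || glu < 0) {
    stop("glu must be a nonnegative concentration (uM)", call. = FALSE)
  }
  parts <- generator_parts(scheme)
  Q <- parts$Q0 + glu * parts$Q1
  dimnames(Q) <- list(ampar_states, ampar_states)
  Q
}

# Split the generator into concentration-independent (Q0) and
# concentration-proportional (Q1) parts: Q(c) = Q0 + c * Q1.
generator_parts <- function(scheme) {
  n <- length(ampar_states)
  Q0 <- matrix(0, n, n)
  Q1 <- matrix(0, n, n)
  idx <- stats::setNames(seq_len(n), ampar_states)
  tr <- scheme$transitions
  for (row in seq_len(nrow(tr))) {
    i <- idx[[tr$from[row]]]
    j <- idx[[tr$to[row]]]
    if (tr$ligand_order[row] == 1) {
      Q1[j, i] <- Q1[j, i] + tr$rate[row]
    } else {
      Q0[j, i] <- Q0[j, i] + tr$rate[row]
    }
  }
  diag(Q0) <- diag(Q0) - colSums(Q0)
  diag(Q1) <- diag(Q1) - colSums(Q1)
  list(Q0 = Q0, Q1 = Q1)
}
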