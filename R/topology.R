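#' Helix-level topology of one construct
#'
#' A `topology` is the ordered list of helix-class labels of one construct
#' plus the class label of each interface between adjacent helices. If
#' `interfaces` is omitted the canonical CTPR typing rule is applied: the
#' interface adjacent to a leading N-cap `"A"` helix is A-typed, the
#' interface preceding a trailing C-cap `"S"` helix is S-typed, and all other
#' interfaces are I-typed. Deletion constructs that start with an internal
#' helix have no A-typed interface; constructs that end internally have no
#' S-typed interface.
#'
#' @param helices character vector of helix-class labels, length >= 1.
#' @param interfaces character vector of interface-class labels, length
#'   `length(helices) - 1`, or `NULL` to apply the canonical rule.
#' @param construct_id identifier, e.g. `"CTPR3"`, `"CTPRa2dS"`.
#' @return An object of class `topology`.
#' @export
#' @examples
#' topology(c("A", "I", "I", "I", "S"), construct_id = "CTPR2")
topology <- function(helices, interfaces = NULL, construct_id = "") {
  helices <- as.character(helices)
  if (length(helices) < 1L) stop("a topology needs at least one helix", call. = FALSE)
  if (is.null(interfaces)) interfaces <- canonical_interfaces(helices)
  interfaces <- as.character(interfaces)
  if (length(interfaces) != length(helices) - 1L)
    stop("need exactly one interface per adjacent helix pair", call. = FALSE)
  structure(list(construct_id = construct_id, helices = helices,
                 interfaces = interfaces),
            class = "topology")
}

#' @rdname topology
#' @export
canonical_interfaces <- function(helices) {
  n <- length(helices)
  if (n < 2L) return(character(0))
  int <- rep("I", n - 1L)
  if (helices[1L] == "A") int[1L] <- "A"
  if (helices[n] == "S") int[n - 1L] <- "S"
  int
}

#' @export
print.topology <- function(x, ...) {
  cat("Construct ", if (nzchar(x$construct_id)) x$construct_id else "<unnamed>",
      ": ", length(x$helices), " helices\n", sep = "")
  cat("  helices:    ", paste(x$helices, collapse = "-"), "\n", sep = "")
  if (length(x$interfaces))
    cat("  interfaces: ", paste(x$interfaces, collapse = "-"), "\n", sep = "")
  invisible(x)
}

n_helices <- function(top) length(top$helices)

#' Build a canonical CTPR-family topology
#'
#' A full-length construct with `n_repeats` TPR motifs has `2 * n_repeats + 1`
#' helices: the N-cap A-helix, `2 * n_repeats - 1` internal helices, and the
#' C-cap S-helix. Dropping the N-cap (`n_cap = FALSE`, a "dA" construct) or
#' the C-cap (`c_cap = FALSE`, "dS") removes that terminal helix and its
#' interface, leaving `2 * n_repeats` helices.
#'
#' @param n_repeats number of TPR motifs, >= 1.
#' @param series `"CTPRn"` (PNN linker) or `"CTPRan"` (PRS linker); only the
#'   construct identifier differs, parameters are bound separately via an
#'   [energy_model()].
#' @param n_cap,c_cap logical; keep the N-cap / C-cap helix?
#' @return a [topology()].
#' @export
#' @examples
#' build_topology(3)                      # CTPR3: A-I-I-I-I-I-S
#' build_topology(2, c_cap = FALSE)       # CTPR2dS: A-I-I-I
build_topology <- function(n_repeats, series = c("CTPRn", "CTPRan"),
                           n_cap = TRUE, c_cap = TRUE) {
  series <- match.arg(series)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  helices <- c(if (n_cap) "A", rep("I", 2L * n_repeats - 1L), if (c_cap) "S")
  id <- paste0(if (series == "CTPRn") "CTPR" else "CTPRa", n_repeats,
               if (!n_cap) "dA", if (!c_cap) "dS")
  topology(helices, construct_id = id)
}

#' Parse a CTPR construct identifier
#'
#' Understands the family nomenclature used throughout the package:
#' `CTPR<k>`, `CTPRa<k>`, optional suffix `dA` (N-cap deletion), `dS` (C-cap
#' deletion) or `sw` (switch chimera). ASCII `d` stands in for the Greek
#' capital delta of the printed names.
#'
#' @param id a construct identifier string.
#' @return a list with elements `series`, `n_repeats`, `n_cap`, `c_cap`,
#'   `switch`.
#' @export
parse_construct_id <- function(id) {
  m <- regmatches(id, regexec("^CTPR(a?)([0-9]+)(dA|dS|sw)?$", id))[[1L]]
  if (length(m) == 0L)
    stop("cannot parse construct identifier: '", id, "'", call. = FALSE)
  suffix <- m[4L]
  list(series = if (m[2L] == "a") "CTPRan" else "CTPRn",
       n_repeats = as.integer(m[3L]),
       n_cap = !identical(suffix, "dA"),
       c_cap = !identical(suffix, "dS"),
       switch = identical(suffix, "sw"))
}

#' Compose a switch chimera: stable core, destabilised C-cap
#'
#' Builds a full-length topology of `n_repeats` motifs and an energy model
#' whose A- and I-class parameters come from `core_model` while all S-class
#' parameters (intrinsic, interfacial, and the associated m-values) come from
#' `cap_model`. The S-typed interface travels with the cap because the switch
#' mutation sits in the junction between the last motif and the C-cap helix.
#'
#' @param core_model an [energy_model()] supplying A- and I-class parameters.
#' @param cap_model an [energy_model()] supplying S-class parameters.
#' @param n_repeats number of TPR motifs.
#' @return list with elements `topology` and `model`.
#' @export
#' @examples
#' sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(), 3)
#' sw$topology
build_switch_chimera <- function(core_model, cap_model, n_repeats) {
  stopifnot(inherits(core_model, "energy_model"),
            inherits(cap_model, "energy_model"))
  if (core_model$variant != cap_model$variant)
    stop("core and cap models must share the same variant", call. = FALSE)
  if (core_model$temperature != cap_model$temperature ||
      core_model$gas_constant != cap_model$gas_constant)
    stop("core and cap models must share temperature and gas constant",
         call. = FALSE)
  check_class(core_model, c("A", "I"))
  check_class(cap_model, "S")
  take <- function(field) {
    v <- core_model[[field]][c("A", "I")]
    c(v, S = unname(cap_model[[field]][["S"]]))
  }
  variant <- core_model$variant
  margs <- switch(variant,
    both_m      = list(m_intr = take("m_intr"), m_int = take("m_int")),
    interface_m = list(m_int = take("m_int")),
    intrinsic_m = list(m_intr = take("m_intr")))
  model <- do.call(energy_model, c(
    list(G_intr = take("G_intr"), G_int = take("G_int"), variant = variant,
         temperature = core_model$temperature,
         gas_constant = core_model$gas_constant),
    margs))
  top <- build_topology(n_repeats)
  top$construct_id <- paste0("CTPR", n_repeats, "sw")
  list(topology = top, model = model)
}

#' Grow or shrink a CTPR topology by whole motifs
#'
#' Inserts `2 * extra_repeats` internal helices (with I-typed interfaces)
#' before the C-cap, or removes them when `extra_repeats` is negative.
#'
#' @param top a canonical CTPR [topology()].
#' @param extra_repeats integer number of motifs to add (may be negative).
#' @return a [topology()].
#' @export
#' @examples
#' extend_repeats(build_topology(3), 7)   # CTPR10, 21 helices
extend_repeats <- function(top, extra_repeats) {
  stopifnot(inherits(top, "topology"))
  extra_repeats <- as.integer(extra_repeats)
  if (extra_repeats == 0L) return(top)
  info <- tryCatch(parse_construct_id(top$construct_id), error = function(e) NULL)
  n_int <- sum(top$helices == "I")
  if (n_int + 2L * extra_repeats < 1L ||
      (!is.null(info) && info$n_repeats + extra_repeats < 1L))
    stop("resulting construct would have fewer than one repeat", call. = FALSE)
  has_s <- top$helices[n_helices(top)] == "S"
  cut <- if (has_s) n_helices(top) - 1L else n_helices(top)
  helices <- append(top$helices, rep("I", max(0L, 2L * extra_repeats)), after = cut)
  if (extra_repeats < 0L)
    helices <- c(top$helices[seq_len(cut + 2L * extra_repeats)],
                 if (has_s) "S")
  id <- top$construct_id
  if (!is.null(info)) {
    sw <- grepl("sw$", id)
    id <- paste0(if (info$series == "CTPRn") "CTPR" else "CTPRa",
                 info$n_repeats + extra_repeats,
                 if (!info$n_cap) "dA", if (!info$c_cap) "dS", if (sw) "sw")
  }
  topology(helices, construct_id = id)
}
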