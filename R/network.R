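#' Blood and wall material parameters for the proximal vessels
#'
#' Bundles the constants of the proximal 1D model: blood density and viscosity,
#' the power-law velocity-profile exponent, and the uniform arterial and venous
#' wall stiffnesses \eqn{K = Eh/r_0} (dyn/cm^2). Defaults put the stiffnesses at
#' the midpoints of their prior bounds (see [parameter_prior()]).
#'
#' @param K_A proximal arterial stiffness Eh/r0, dyn/cm^2.
#' @param K_V proximal venous stiffness, dyn/cm^2.
#' @param rho blood density, g/cm^3.
#' @param nu kinematic viscosity, cm^2/s.
#' @param mu dynamic viscosity, g/(cm s); must equal `rho * nu` within 1%.
#' @param gamma dimensionless velocity-profile exponent (blunt profile).
#' @return A list of class `"material_parameters"`.
#' @export
material_parameters <- function(K_A = 8.0e5, K_V = 8.525e5, rho = 1.055,
                                nu = 3.03e-2, mu = 0.032, gamma = 9) {
  vals <- c(K_A = K_A, K_V = K_V, rho = rho, nu = nu, mu = mu, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material parameters must be finite and strictly positive")
  if (abs(mu - rho * nu) > 0.01 * mu)
    stop(sprintf("inconsistent viscosities: mu = %.4g but rho*nu = %.4g (>1%% apart)",
                 mu, rho * nu))
  structure(list(K_A = K_A, K_V = K_V, rho = rho, nu = nu, mu = mu,
                 gamma = gamma), class = "material_parameters")
}

#' Load and validate a proximal vessel network
#'
#' Reads a table of vessel segments (or a CSV file with columns
#' `name,length_cm,radius_cm,side,parent,daughter1,daughter2,terminal_partner`)
#' describing the bifurcating proximal arterial and venous trees, checks the
#' topology, and returns a validated network object. Terminal arteries are
#' paired one-to-one with their venous counterparts across the microcirculation;
#' each pair anchors one two-sided structured-tree bed.
#'
#' Validation errors name the offending segment: non-positive geometry,
#' a daughter count other than 0 or 2, cycles in the parent links, inconsistent
#' parent/daughter cross-references, and dangling or non-bijective terminal
#' partner references are all rejected.
#'
#' @param table a data.frame with the columns above, or the path of a CSV file.
#' @param materials a [material_parameters()] object.
#' @return An object of class `"proximal_network"`: the segment table plus the
#'   inlet label, venous outlet labels, the terminal pair table and materials.
#' @export
load_network <- function(table, materials = material_parameters()) {
  if (is.character(table)) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE,
                             colClasses = "character")
    table$length_cm <- as.numeric(table$length_cm)
    table$radius_cm <- as.numeric(table$radius_cm)
  }
  need <- c("name", "length_cm", "radius_cm", "side", "parent",
            "daughter1", "daughter2", "terminal_partner")
  if (!all(need %in% names(table)))
    stop("network table must have columns: ", paste(need, collapse = ", "))
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in c("parent", "daughter1", "daughter2", "terminal_partner")) {
    tab[[col]] <- as.character(tab[[col]])
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  if (anyDuplicated(tab$name))
    stop("duplicate segment name: ", tab$name[duplicated(tab$name)][1])
  bad <- tab$name[!(tab$length_cm > 0) | !(tab$radius_cm > 0)]
  if (length(bad)) stop("non-positive length or radius in segment '", bad[1], "'")
  if (!all(tab$side %in% c("arterial", "venous")))
    stop("side must be 'arterial' or 'venous'")

  has1 <- nzchar(tab$daughter1); has2 <- nzchar(tab$daughter2)
  if (any(has1 != has2))
    stop("daughter count not in {0,2} for segment '", tab$name[has1 != has2][1], "'")
  for (col in c("parent", "daughter1", "daughter2", "terminal_partner")) {
    ref <- tab[[col]]
    miss <- nzchar(ref) & !(ref %in% tab$name)
    if (any(miss))
      stop("segment '", tab$name[miss][1], "' references unknown segment '",
           ref[miss][1], "' in column ", col)
  }

  # parent/daughter cross-consistency
  for (i in seq_len(nrow(tab))) {
    p <- tab$parent[i]
    if (nzchar(p)) {
      drow <- tab[tab$name == p, ]
      if (!(tab$name[i] %in% c(drow$daughter1, drow$daughter2)))
        stop("segment '", tab$name[i], "' names parent '", p,
             "' which does not list it as a daughter")
    }
  }
  # cycle check by walking parent links
  for (i in seq_len(nrow(tab))) {
    seen <- character(); cur <- tab$name[i]
    while (nzchar(cur)) {
      if (cur %in% seen) stop("cycle in parent links at segment '", cur, "'")
      seen <- c(seen, cur)
      cur <- tab$parent[tab$name == cur]
    }
  }

  term_art <- tab$name[tab$side == "arterial" & !has1]
  # terminal_partner set iff terminal artery or venous attachment point
  for (i in seq_len(nrow(tab))) {
    tp <- tab$terminal_partner[i]
    terminal <- !has1[i]
    if (terminal && !nzchar(tp))
      stop("terminal segment '", tab$name[i], "' lacks a terminal partner")
    if (!terminal && nzchar(tp))
      stop("non-terminal segment '", tab$name[i], "' has a terminal partner")
  }
  pairs <- data.frame(artery = term_art,
                      vein = tab$terminal_partner[match(term_art, tab$name)],
                      stringsAsFactors = FALSE)
  # bijection: each partner venous, terminal, and pointing back
  for (k in seq_len(nrow(pairs))) {
    v <- pairs$vein[k]
    vrow <- tab[tab$name == v, ]
    if (vrow$side != "venous" || nzchar(vrow$daughter1) ||
        vrow$terminal_partner != pairs$artery[k])
      stop("dangling terminal pair reference: '", pairs$artery[k], "' <-> '", v, "'")
  }
  if (anyDuplicated(pairs$vein))
    stop("terminal pairing is not a bijection (vein '",
         pairs$vein[duplicated(pairs$vein)][1], "' reused)")
  pairs$root_radius <- tab$radius_cm[match(pairs$artery, tab$name)]

  art_roots <- tab$name[tab$side == "arterial" & !nzchar(tab$parent)]
  ven_roots <- tab$name[tab$side == "venous" & !nzchar(tab$parent)]
  if (length(art_roots) != 1)
    stop("expected exactly one arterial root, found ", length(art_roots))

  net <- structure(list(segments = tab, inlet = art_roots,
                        venous_outlets = ven_roots, pairs = pairs,
                        materials = materials),
                   class = "proximal_network")
  net
}

#' Default proximal pulmonary network
#'
#' The 15-artery / 12-vein proximal pulmonary network (main pulmonary artery to
#' the segmental level, plus two generations of pulmonary veins) with eight
#' terminal artery-vein pairs, shipped as a package fixture.
#'
#' @param materials a [material_parameters()] object; by default the arterial
#'   and venous stiffnesses sit at the midpoints of their prior bounds.
#' @return A `"proximal_network"` object.
#' @export
default_network <- function(materials = material_parameters()) {
  path <- system.file("extdata", "proximal_network.csv", package = "pulmnet",
                      mustWork = TRUE)
  load_network(path, materials)
}

#' Write a proximal network back to CSV
#'
#' Inverse of [load_network()]: the written file round-trips field-for-field.
#'
#' @param network a `"proximal_network"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "proximal_network"))
  utils::write.csv(network$segments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.proximal_network <- function(x, ...) {
  tab <- x$segments
  cat("Proximal vascular network:", sum(tab$side == "arterial"), "arteries,",
      sum(tab$side == "venous"), "veins,", nrow(x$pairs), "terminal pairs\n")
  cat("inlet:", x$inlet, "; venous outlets:",
      paste(x$venous_outlets, collapse = ", "), "\n")
  invisible(x)
}

# number of terminal (leaf) arterial segments reaching the inlet by parent links
.check_leaf_paths <- function(network) {
  tab <- network$segments
  leaves <- tab$name[tab$side == "arterial" & !nzchar(tab$daughter1)]
  ok <- vapply(leaves, function(nm) {
    cur <- nm
    repeat {
      p <- tab$parent[tab$name == cur]
      if (!nzchar(p)) return(cur == network$inlet)
      cur <- p
    }
  }, logical(1))
  all(ok)
}
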