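# Network input/output: a full-fidelity native JSON description and an SBML
# Level 3 subset.  The native format round-trips bit-exactly for the
# catalogued rate-law kinds; custom closures are not serialisable.

law_to_list <- function(law) {
  switch(law$kind,
    mass_action = list(kind = "mass_action",
                       params = list(k = law$k, name = law$params$name)),
    mm_irreversible = ,
    mm_competitive = ,
    mm_noncompetitive = ,
    mm_uncompetitive = list(
      kind = law$kind,
      params = list(V = law$params$V, Km = as.list(law$params$Km),
                    substrates = as.list(law$params$substrates),
                    sites = lapply(law$params$sites, as.list),
                    inhibitor = law$params$inhibitor, Ki = law$params$Ki)),
    rev_mm_halfreaction = list(
      kind = "rev_mm_halfreaction",
      params = list(V = law$params$V, Km = as.list(law$params$Km),
                    substrates = as.list(law$params$substrates),
                    products = as.list(law$params$products),
                    sites = lapply(law$params$sites, as.list),
                    role = law$params$role)),
    hill = list(kind = "hill",
                params = list(V = law$params$V, K = law$params$K,
                              n = law$params$n, species = law$params$species)),
    stop("rate laws of kind '", law$kind,
         "' cannot be serialised (custom closures)"))
}

list_to_law <- function(lst) {
  params <- lst$params
  if (!is.null(params$Km)) params$Km <- unlist(params$Km)
  if (!is.null(params$substrates)) params$substrates <- unlist(params$substrates)
  if (!is.null(params$products)) params$products <- unlist(params$products)
  if (!is.null(params$sites)) params$sites <- lapply(params$sites, unlist)
  make_rate_law(lst$kind, params)
}

stoich_to_list <- function(stoich) as.list(stoich[stoich != 0])

network_to_list <- function(net) {
  stopifnot(inherits(net, "crn"))
  Z <- complex_matrix(net)
  reactions <- lapply(net$reactions, function(r) {
    sub <- net$complexes[[r$substrate]]
    prod <- net$complexes[[r$product]]
    list(substrate = stoich_to_list(sub), product = stoich_to_list(prod),
         pair = if (is.na(r$pair)) NULL else r$pair,
         law = law_to_list(r$law))
  })
  boundary <- lapply(net$boundary, function(bf)
    list(complex = stoich_to_list(net$complexes[[bf$complex]]),
         type = bf$type, k = bf$k))
  list(format = "crnreduce-network", version = 1L,
       species = lapply(seq_len(nrow(net$species)), function(i)
         list(id = net$species$id[i], name = net$species$name[i],
              x0 = net$species$x0[i], fixed = net$species$fixed[i])),
       reactions = reactions,
       boundary_fluxes = boundary)
}

list_to_network <- function(lst) {
  if (!identical(lst$format, "crnreduce-network"))
    stop("not a crnreduce network description")
  species <- do.call(rbind, lapply(lst$species, function(s)
    data.frame(id = s$id, name = if (is.null(s$name)) s$id else s$name,
               x0 = s$x0, fixed = isTRUE(s$fixed),
               stringsAsFactors = FALSE)))
  specs <- list()
  i <- 1L
  recs <- lst$reactions
  while (i <= length(recs)) {
    r <- recs[[i]]
    sub <- unlist(r$substrate)
    prod <- unlist(r$product)
    if (!is.null(r$pair) && i < length(recs) &&
        identical(recs[[i + 1L]]$pair, r$pair)) {
      specs[[length(specs) + 1L]] <-
        reversible_reaction(sub, prod,
                            list(fwd = list_to_law(r$law),
                                 rev = list_to_law(recs[[i + 1L]]$law)))
      i <- i + 2L
    } else {
      specs[[length(specs) + 1L]] <- rxn(sub, prod, list_to_law(r$law))
      i <- i + 1L
    }
  }
  boundary <- lapply(lst$boundary_fluxes, function(bf)
    boundary_flux(unlist(bf$complex), bf$type, bf$k))
  reaction_network(species = species, reactions = specs,
                   boundary_fluxes = boundary)
}

network_digest <- function(net) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(network_to_list(net), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write a network (or reduced network) to the native JSON format
#'
#' The native description carries species, sparse complex stoichiometries,
#' directed reactions with their rate-law kind and parameters (reversible
#' pairs linked by a pair id) and boundary fluxes; it round-trips
#' bit-exactly. A reduced model adds a `reduction` block (deleted complexes,
#' frozen species values, a hash of the parent description).
#'
#' @param model a `crn` or `crn_reduced` object.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_network_json <- function(model, path) {
  lst <- if (inherits(model, "crn_reduced")) {
    parent_lst <- network_to_list(model$parent)
    labs <- vapply(model$parent$complexes, complex_label, character(1))
    c(parent_lst,
      list(reduction = list(
        deleted = as.list(model$deleted),
        deleted_labels = as.list(labs[model$deleted]),
        frozen = as.list(model$frozen),
        parent_hash = network_digest(model$parent))))
  } else network_to_list(model)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network from the native JSON format
#'
#' @param path file written by [write_network_json()].
#' @return A `crn` network, or a `crn_reduced` model when the file carries a
#'   reduction block.
#' @export
read_network_json <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  net <- list_to_network(lst)
  if (!is.null(lst$reduction))
    delete_complexes(net, unlist(lst$reduction$deleted),
                     frozen = unlist(lst$reduction$frozen))
  else net
}

# --- SBML Level 3 subset ----------------------------------------------------

CRN_NS <- "https://crnreduce.r-lib.org/ns"
SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"

#' Write a network to an SBML Level 3 file (subset)
#'
#' Species, reactions and stoichiometries are written as standard SBML; the
#' factored rate-law parameterisation (kind, constants, shared-denominator
#' pairing) and the boundary fluxes travel in a package annotation namespace
#' attached to each kinetic law and to the model. A reduced model embeds its
#' reduction block (deleted complexes, frozen values) as a model annotation,
#' since no standard kinetic law expresses a state-dependent Schur
#' complement — a documented limitation of the export.
#'
#' @param model a `crn` or `crn_reduced` object.
#' @param path output file path.
#' @param model_id SBML model id.
#' @return Invisibly, the path.
#' @export
write_sbml <- function(model, path, model_id = "crn_model") {
  net <- if (inherits(model, "crn_reduced")) model$parent else model
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:crn" = CRN_NS,
                            level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id,
                             timeUnits = "minute")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true",
                      size = "1")
  losp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(net$species)))
    xml2::xml_add_child(losp, "species",
                        id = net$species$id[i],
                        name = net$species$name[i],
                        compartment = "cell",
                        initialConcentration = format(net$species$x0[i], digits = 17),
                        constant = tolower(as.character(net$species$fixed[i])),
                        boundaryCondition = tolower(as.character(net$species$fixed[i])),
                        hasOnlySubstanceUnits = "false")
  lorx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    rx <- xml2::xml_add_child(lorx, "reaction", id = paste0("r", j),
                              reversible = "false", fast = "false")
    sub <- net$complexes[[r$substrate]]
    prod <- net$complexes[[r$product]]
    lor <- xml2::xml_add_child(rx, "listOfReactants")
    for (s in names(sub)[sub != 0])
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = as.character(sub[[s]]),
                          constant = "true")
    lop <- xml2::xml_add_child(rx, "listOfProducts")
    for (s in names(prod)[prod != 0])
      xml2::xml_add_child(lop, "speciesReference", species = s,
                          stoichiometry = as.character(prod[[s]]),
                          constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    ann <- xml2::xml_add_child(kl, "annotation")
    rec <- law_to_list(r$law)
    rec$pair <- if (is.na(r$pair)) NULL else r$pair
    node <- xml2::xml_add_child(ann, "crn:rateLaw")
    xml2::xml_set_text(node, as.character(
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)))
  }
  extra <- list()
  if (length(net$boundary) > 0)
    extra$boundary_fluxes <- lapply(net$boundary, function(bf)
      list(complex = stoich_to_list(net$complexes[[bf$complex]]),
           type = bf$type, k = bf$k))
  if (inherits(model, "crn_reduced")) {
    labs <- vapply(net$complexes, complex_label, character(1))
    extra$reduction <- list(deleted = as.list(model$deleted),
                            deleted_labels = as.list(labs[model$deleted]),
                            frozen = as.list(model$frozen))
  }
  if (length(extra) > 0) {
    mann <- xml2::xml_add_child(mdl, "annotation")
    node <- xml2::xml_add_child(mann, "crn:networkExtras")
    xml2::xml_set_text(node, as.character(
      jsonlite::toJSON(extra, auto_unbox = TRUE, digits = NA)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network from an SBML Level 3 file (subset)
#'
#' Reads species, stoichiometries and the catalogued rate-law
#' parameterisations written by [write_sbml()]. A kinetic law without the
#' package's rate-law annotation (e.g. raw MathML) raises an explicit
#' unsupported-law error naming the reaction.
#'
#' @param path SBML file path.
#' @return A `crn` network or `crn_reduced` model.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("malformed SBML: no species")
  species <- do.call(rbind, lapply(sp_nodes, function(nd)
    data.frame(id = xml2::xml_attr(nd, "id"),
               name = {
                 nm <- xml2::xml_attr(nd, "name")
                 if (is.na(nm)) xml2::xml_attr(nd, "id") else nm
               },
               x0 = as.numeric(xml2::xml_attr(nd, "initialConcentration")),
               fixed = identical(xml2::xml_attr(nd, "boundaryCondition"), "true"),
               stringsAsFactors = FALSE)))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  recs <- lapply(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    read_side <- function(tag) {
      refs <- xml2::xml_find_all(nd, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      st <- vapply(refs, function(rf) {
        s <- xml2::xml_attr(rf, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, numeric(1))
      stats::setNames(st, vapply(refs, xml2::xml_attr, character(1), "species"))
    }
    ann <- xml2::xml_find_first(nd, sprintf(
      ".//*[local-name()='kineticLaw']//*[local-name()='rateLaw' and namespace-uri()='%s']",
      CRN_NS))
    if (inherits(ann, "xml_missing"))
      stop("unsupported kinetic law in reaction '", rid,
           "': no catalogued rate-law annotation (arbitrary MathML is not",
           " recognised)")
    rec <- jsonlite::fromJSON(xml2::xml_text(ann), simplifyVector = FALSE)
    list(substrate = as.list(read_side("listOfReactants")),
         product = as.list(read_side("listOfProducts")),
         pair = rec$pair, law = rec[c("kind", "params")])
  })
  extras_node <- xml2::xml_find_first(doc, sprintf(
    ".//*[local-name()='model']/*[local-name()='annotation']/*[local-name()='networkExtras' and namespace-uri()='%s']",
    CRN_NS))
  extras <- if (!inherits(extras_node, "xml_missing"))
    jsonlite::fromJSON(xml2::xml_text(extras_node), simplifyVector = FALSE)
  else list()
  lst <- list(format = "crnreduce-network", version = 1L,
              species = lapply(seq_len(nrow(species)), function(i)
                as.list(species[i, ])),
              reactions = recs,
              boundary_fluxes = if (is.null(extras$boundary_fluxes)) list()
                                else extras$boundary_fluxes)
  net <- list_to_network(lst)
  if (!is.null(extras$reduction))
    delete_complexes(net, unlist(extras$reduction$deleted),
                     frozen = unlist(extras$reduction$frozen))
  else net
}

#' Read a network from a file, dispatching on extension
#' @param path `.json` (native) or `.xml`/`.sbml` file.
#' @return A `crn` or `crn_reduced` object.
#' @export
read_network <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_network_json(path),
         xml = ,
         sbml = read_sbml(path),
         stop("unrecognised network file extension: .", ext))
}
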