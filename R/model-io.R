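# Versioned JSON model format (schema shipped at
# inst/extdata/model-schema.json). YAML is accepted as a reading dialect
# producing identical models; output is always canonical JSON.

MODEL_FORMAT_VERSION <- "1.0"

warn_unknown_keys <- function(obj, known, where) {
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning(sprintf("ignoring unknown key%s at %s: %s",
                    if (length(extra) > 1L) "s" else "", where,
                    paste(extra, collapse = ", ")), call. = FALSE)
}

need_key <- function(obj, key, where) {
  if (is.null(obj[[key]]))
    stop(sprintf("schema violation at %s: required key '%s' missing",
                 where, key), call. = FALSE)
  obj[[key]]
}

chr1 <- function(x, where) {
  if (!(is.character(x) || is.numeric(x)) || length(x) != 1L)
    stop(sprintf("schema violation at %s: expected a string", where),
         call. = FALSE)
  as.character(x)
}

#' Parse a model document
#'
#' Reads the versioned JSON model dialect (or YAML, as a convenience) into
#' a fully cross-linked [reaction_model()]. Unknown keys are ignored with a
#' warning. The parsed model is validated: dangling references or invariant
#' violations raise an error that lists every offending path.
#'
#' @param text a single string, character vector of lines, or connection
#'   holding the document.
#' @param format `"json"` or `"yaml"`.
#' @return a validated [reaction_model()].
#' @seealso [serialize_model()], [read_model()]
#' @export
parse_model <- function(text, format = c("json", "yaml")) {
  format <- match.arg(format)
  if (inherits(text, "connection")) text <- readLines(text, warn = FALSE)
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  doc <- if (format == "json")
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  else
    yaml::yaml.load(text)
  if (!is.list(doc))
    stop("schema violation at /: document root must be an object",
         call. = FALSE)
  warn_unknown_keys(doc, c("format_version", "molecules", "species", "rules",
                           "metadata"), "/")
  fv <- chr1(need_key(doc, "format_version", "/"), "/format_version")

  molecules <- lapply(seq_along(doc$molecules), function(i) {
    m <- doc$molecules[[i]]
    where <- sprintf("/molecules/%d", i)
    warn_unknown_keys(m, c("name", "components"), where)
    comps <- lapply(seq_along(m$components), function(j) {
      cm <- m$components[[j]]
      cw <- sprintf("%s/components/%d", where, j)
      warn_unknown_keys(cm, c("name", "state_variables", "binding_sites"), cw)
      mol_component(chr1(need_key(cm, "name", cw), cw),
                    state_variables = unlist(cm$state_variables),
                    binding_sites = unlist(cm$binding_sites))
    })
    molecule(chr1(need_key(m, "name", where), where), comps)
  })

  species <- lapply(seq_along(doc$species), function(i) {
    s <- doc$species[[i]]
    where <- sprintf("/species/%d", i)
    warn_unknown_keys(s, c("name", "molecule_instances", "structural_bonds",
                           "complexes"), where)
    mi <- do.call(rbind, lapply(s$molecule_instances, function(x)
      data.frame(instance_id = chr1(need_key(x, "instance_id", where), where),
                 molecule = chr1(need_key(x, "molecule", where), where),
                 stringsAsFactors = FALSE)))
    if (is.null(mi))
      mi <- data.frame(instance_id = character(), molecule = character(),
                       stringsAsFactors = FALSE)
    bonds <- lapply(s$structural_bonds, function(b) as.integer(unlist(b)))
    cxs <- lapply(seq_along(s$complexes), function(j) {
      cx <- s$complexes[[j]]
      cw <- sprintf("%s/complexes/%d", where, j)
      warn_unknown_keys(cx, c("name", "states"), cw)
      st <- do.call(rbind, lapply(cx$states, function(x)
        data.frame(instance_id = chr1(need_key(x, "instance_id", cw), cw),
                   component = chr1(need_key(x, "component", cw), cw),
                   state_variable = chr1(need_key(x, "state_variable", cw), cw),
                   value = chr1(need_key(x, "value", cw), cw),
                   stringsAsFactors = FALSE)))
      if (is.null(st)) st <- data.frame()
      species_complex(chr1(need_key(cx, "name", cw), cw), st)
    })
    complex_species(chr1(need_key(s, "name", where), where), mi, bonds, cxs)
  })

  rules <- lapply(seq_along(doc$rules), function(i) {
    r <- doc$rules[[i]]
    where <- sprintf("/rules/%d", i)
    warn_unknown_keys(r, c("name", "category", "reactants", "products",
                           "bond_sites", "rate_constant"), where)
    pairs <- function(xs) {
      out <- do.call(rbind, lapply(xs, function(x)
        data.frame(species = chr1(need_key(x, "species", where), where),
                   complex = chr1(need_key(x, "complex", where), where),
                   stringsAsFactors = FALSE)))
      if (is.null(out))
        out <- data.frame(species = character(), complex = character(),
                          stringsAsFactors = FALSE)
      out
    }
    bs <- NULL
    if (!is.null(r$bond_sites))
      bs <- lapply(r$bond_sites, function(x)
        binding_site_ref(chr1(need_key(x, "species", where), where),
                         need_key(x, "site_index", where)))
    rate <- if (is.null(r$rate_constant)) 0 else as.numeric(r$rate_constant)
    reaction_rule(chr1(need_key(r, "name", where), where),
                  chr1(need_key(r, "category", where), where),
                  pairs(r$reactants), pairs(r$products),
                  bond_sites = bs, rate_constant = rate)
  })

  metadata <- if (is.null(doc$metadata)) list() else doc$metadata
  model <- reaction_model(molecules, species, rules, metadata,
                          format_version = fv)
  assert_valid_model(model)
  model
}

model_to_document <- function(model) {
  comp_doc <- function(c) list(
    name = jsonlite::unbox(c$name),
    state_variables = as.list(c$state_variables),
    binding_sites = as.list(c$binding_sites))
  mol_doc <- function(m) list(
    name = jsonlite::unbox(m$name),
    components = lapply(m$components, comp_doc))
  cx_doc <- function(cx) list(
    name = jsonlite::unbox(cx$name),
    states = lapply(seq_len(nrow(cx$states)), function(i) list(
      instance_id = jsonlite::unbox(cx$states$instance_id[i]),
      component = jsonlite::unbox(cx$states$component[i]),
      state_variable = jsonlite::unbox(cx$states$state_variable[i]),
      value = jsonlite::unbox(cx$states$value[i]))))
  sp_doc <- function(s) list(
    name = jsonlite::unbox(s$name),
    molecule_instances = lapply(seq_len(nrow(s$molecule_instances)),
      function(i) list(
        instance_id = jsonlite::unbox(s$molecule_instances$instance_id[i]),
        molecule = jsonlite::unbox(s$molecule_instances$molecule[i]))),
    structural_bonds = lapply(s$structural_bonds, as.integer),
    complexes = lapply(s$complexes, cx_doc))
  rule_doc <- function(r) {
    pairs <- function(p) lapply(seq_len(nrow(p)), function(i) list(
      species = jsonlite::unbox(p$species[i]),
      complex = jsonlite::unbox(p$complex[i])))
    d <- list(name = jsonlite::unbox(r$name),
              category = jsonlite::unbox(r$category),
              reactants = pairs(r$reactants),
              products = pairs(r$products))
    if (!is.null(r$bond_sites))
      d$bond_sites <- lapply(r$bond_sites, function(b) list(
        species = jsonlite::unbox(b$species_name),
        site_index = jsonlite::unbox(b$site_index)))
    d$rate_constant <- jsonlite::unbox(r$rate_constant)
    d
  }
  meta <- model$metadata
  if (length(meta) == 0L) meta <- stats::setNames(list(), character())
  list(format_version = jsonlite::unbox(model$format_version),
       metadata = meta,
       molecules = lapply(unname(model$molecules), mol_doc),
       species = lapply(unname(model$species), sp_doc),
       rules = lapply(unname(model$rules), rule_doc))
}

#' Serialize a model to canonical JSON
#'
#' Produces the versioned JSON model document with canonical key order and
#' the model's normalized (name-sorted) entity order, so equal model
#' content yields byte-identical output regardless of construction order.
#' Invalid models are refused with the aggregated validation report.
#'
#' @param model a valid [reaction_model()].
#' @return a single JSON string (UTF-8, pretty-printed, trailing newline).
#' @export
serialize_model <- function(model) {
  assert_valid_model(model)
  json <- jsonlite::toJSON(model_to_document(model), pretty = 2,
                           digits = NA, null = "null", auto_unbox = TRUE)
  paste0(as.character(json), "\n")
}

#' Read / write model documents on disk
#'
#' `read_model()` dispatches on the file extension (`.yaml`/`.yml` parse as
#' YAML, anything else as JSON); `write_model()` always writes canonical
#' JSON.
#'
#' @param path file path.
#' @param model a valid [reaction_model()].
#' @return `read_model()` a [reaction_model()]; `write_model()` `path`,
#'   invisibly.
#' @export
read_model <- function(path) {
  fmt <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  parse_model(readLines(path, warn = FALSE), format = fmt)
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  writeLines(sub("\n$", "", serialize_model(model)), path)
  invisible(path)
}

#' Field-level model equality
#'
#' Two models are equal when their canonical serializations coincide
#' (entity order is normalized at construction, so this is field-level
#' equality of content).
#'
#' @param a,b [reaction_model()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
model_equal <- function(a, b) identical(serialize_model(a), serialize_model(b))
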