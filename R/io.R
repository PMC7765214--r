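# File formats: cohort CSV + variable-metadata JSON in, network JSON /
# XMLBIF out. CSV dialect: comma-separated, UTF-8, header row required,
# empty cell = missing. Numeric columns declared with cut-points are
# discretized into half-open bins [low, high), the last bin closed above.

#' Variable metadata entry
#'
#' @param name Column name.
#' @param states Ordered state labels.
#' @param role `"feature"` or `"target"`.
#' @param cutpoints Optional strictly increasing numeric cut-points; a
#'   column with k cut-points needs k + 1 states and is discretized into
#'   the bins (-Inf, c1), \[c1, c2), ..., \[ck, Inf).
#' @return A list of class `variable_metadata`.
#' @export
variable_metadata <- function(name, states, role = "feature", cutpoints = NULL) {
  if (!is.null(cutpoints)) {
    cutpoints <- as.numeric(cutpoints)
    if (any(diff(cutpoints) <= 0)) {
      ssbn_stop("validation", "cut-points of '%s' must be strictly increasing", name)
    }
    if (length(states) != length(cutpoints) + 1L) {
      ssbn_stop("validation", "'%s': %d cut-points need %d states", name,
                length(cutpoints), length(cutpoints) + 1L)
    }
  }
  v <- bn_variable(name, states, role = match.arg(role, c("feature", "target")))
  structure(c(unclass(v), list(cutpoints = cutpoints)), class = "variable_metadata")
}

#' Read / write variable metadata (JSON)
#'
#' The metadata file is a JSON array of objects with fields `name`,
#' `states`, optional `role` and optional `cutpoints`; exactly one entry
#' must have role `"target"`.
#'
#' @param path File path.
#' @param metadata List of [variable_metadata()] entries.
#' @return `read_metadata()`: named list of entries; `write_metadata()`:
#'   `path`, invisibly.
#' @export
read_metadata <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) ssbn_stop("parse", "cannot parse metadata '%s': %s",
                                                path, conditionMessage(e)))
  meta <- lapply(raw, function(m) {
    variable_metadata(m$name, unlist(m$states), m$role %||% "feature",
                      if (!is.null(m$cutpoints)) unlist(m$cutpoints))
  })
  names(meta) <- vapply(meta, `[[`, character(1), "name")
  if (sum(vapply(meta, `[[`, character(1), "role") == "target") != 1L) {
    ssbn_stop("configuration", "metadata must declare exactly one target variable")
  }
  meta
}

#' @rdname read_metadata
#' @export
write_metadata <- function(metadata, path) {
  jsonlite::write_json(lapply(unname(metadata), function(m) {
    out <- list(name = m$name, states = m$states, role = m$role)
    if (!is.null(m$cutpoints)) out$cutpoints <- m$cutpoints
    out
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# metadata describing a network's variables (used by the CLI)
metadata_from_network <- function(net) {
  meta <- lapply(bn_vars(net), function(v) {
    variable_metadata(v, bn_states(net, v),
                      if (identical(v, bn_target(net))) "target" else "feature")
  })
  names(meta) <- bn_vars(net)
  meta
}

#' Read a cohort CSV against declared metadata
#'
#' Every used column is validated cell by cell against its declared states
#' (an undeclared label is a validation error naming the offending row and
#' column); empty cells become missing values; columns declared with
#' cut-points are parsed as numbers and discretized.
#'
#' @param csv_path CSV file with a header row.
#' @param metadata A metadata file path or the result of [read_metadata()].
#' @return A `data.frame` of factor columns with attributes `metadata` and
#'   `target`.
#' @export
read_cohort <- function(csv_path, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  raw <- tryCatch(
    utils::read.csv(csv_path, colClasses = "character", check.names = FALSE,
                    na.strings = "", fileEncoding = "UTF-8"),
    error = function(e) ssbn_stop("parse", "cannot read '%s': %s", csv_path,
                                  conditionMessage(e)))
  uncovered <- setdiff(names(raw), names(metadata))
  if (length(uncovered) > 0L) {
    ssbn_stop("configuration", "no metadata for column(s): %s",
              paste(uncovered, collapse = ", "))
  }
  for (v in names(raw)) {
    m <- metadata[[v]]
    col <- raw[[v]]
    if (!is.null(m$cutpoints)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L) {
        ssbn_stop("validation", "column '%s', row %d: '%s' is not numeric",
                  v, bad[1L], col[bad[1L]])
      }
      bin <- findInterval(num, m$cutpoints) + 1L
      raw[[v]] <- factor(m$states[bin], levels = m$states)
    } else {
      bad <- which(!is.na(col) & !(col %in% m$states))
      if (length(bad) > 0L) {
        ssbn_stop("validation",
                  "column '%s', row %d: state '%s' is not declared (allowed: %s)",
                  v, bad[1L], col[bad[1L]], paste(m$states, collapse = ", "))
      }
      raw[[v]] <- factor(col, levels = m$states)
    }
  }
  roles <- vapply(metadata[names(raw)], `[[`, character(1), "role")
  attr(raw, "metadata") <- metadata[names(raw)]
  attr(raw, "target") <- names(roles)[roles == "target"][1L]
  raw
}

#' Write a cohort to CSV
#'
#' @param data Data frame of factors; missing values become empty cells.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- network serialization -------------------------------------------------

#' Write / read a network (JSON or XMLBIF)
#'
#' The JSON schema stores `variables` (name, ordered states, role), `arcs`
#' (parent/child pairs) and `cpts` (child, ordered parents, probability
#' rows in odometer order over the parent list, last parent fastest).
#' XMLBIF 0.3 is produced for interoperability: one `VARIABLE` block per
#' node and one `DEFINITION` per CPT, the `TABLE` listing rows in the same
#' odometer order with child states fastest; the target role is preserved
#' in a `PROPERTY`. Probabilities round-trip at full double precision, and
#' a file whose arcs form a cycle is rejected.
#'
#' @param net A [bayesian_network()].
#' @param path File path.
#' @param format `"json"` or `"xmlbif"`; default inferred from the
#'   extension (`.json` vs `.xml`/`.xmlbif`/`.bif`).
#' @return `write_network()`: `path`, invisibly; `read_network()`: a
#'   [bayesian_network()].
#' @export
write_network <- function(net, path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
         json = write_network_json(net, path),
         xmlbif = write_network_xmlbif(net, path),
         ssbn_stop("configuration", "unknown network format '%s'", format))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
         json = read_network_json(path),
         xmlbif = read_network_xmlbif(path),
         ssbn_stop("configuration", "unknown network format '%s'", format))
}

infer_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.(xml|xmlbif|bif)$", path, ignore.case = TRUE)) "xmlbif"
  else ssbn_stop("configuration", "cannot infer network format from '%s'", path)
}

write_network_json <- function(net, path) {
  s <- net$structure
  obj <- list(
    format = "ssbn-network",
    version = 1L,
    variables = lapply(unname(s$variables), function(v) {
      list(name = v$name, states = as.list(v$states), role = v$role)
    }),
    arcs = unname(apply(s$arcs, 1L, function(r) as.list(unname(r)), simplify = FALSE)),
    cpts = lapply(unname(net$cpts), function(cpt) {
      list(child = cpt$child, parents = as.list(cpt$parents),
           prob = unname(apply(cpt$prob, 1L, as.list, simplify = FALSE)))
    })
  )
  # digits = I(17): full double precision, so probabilities round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

read_network_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) ssbn_stop("parse", "cannot parse '%s': %s",
                                                path, conditionMessage(e)))
  if (is.null(obj$variables) || is.null(obj$cpts)) {
    ssbn_stop("parse", "'%s' is not an ssbn network file", path)
  }
  vars <- lapply(obj$variables, function(v) {
    bn_variable(v$name, unlist(v$states), v$role %||% "feature")
  })
  arcs <- if (length(obj$arcs) > 0L) lapply(obj$arcs, unlist) else NULL
  s <- bn_structure(vars, arcs)
  cpts <- lapply(obj$cpts, function(cpt) {
    prob <- do.call(rbind, lapply(cpt$prob, unlist))
    bn_cpt(cpt$child, unlist(cpt$parents) %||% character(0), prob)
  })
  bayesian_network(s, cpts)
}

write_network_xmlbif <- function(net, path) {
  s <- net$structure
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", "ssbn")
  for (v in s$variables) {
    vn <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(vn, "NAME", v$name)
    for (st in v$states) xml2::xml_add_child(vn, "OUTCOME", st)
    if (v$role == "target") xml2::xml_add_child(vn, "PROPERTY", "role = target")
  }
  for (cpt in net$cpts) {
    dn <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(dn, "FOR", cpt$child)
    for (p in cpt$parents) xml2::xml_add_child(dn, "GIVEN", p)
    tab <- paste(sprintf("%.17g", as.vector(t(cpt$prob))), collapse = " ")
    xml2::xml_add_child(dn, "TABLE", tab)
  }
  xml2::write_xml(doc, path)
}

read_network_xmlbif <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) ssbn_stop("parse", "cannot parse '%s': %s",
                                                path, conditionMessage(e)))
  vnodes <- xml2::xml_find_all(doc, ".//VARIABLE")
  if (length(vnodes) == 0L) ssbn_stop("parse", "'%s' has no VARIABLE blocks", path)
  vars <- lapply(vnodes, function(vn) {
    name <- xml2::xml_text(xml2::xml_find_first(vn, "./NAME"))
    states <- xml2::xml_text(xml2::xml_find_all(vn, "./OUTCOME"))
    props <- xml2::xml_text(xml2::xml_find_all(vn, "./PROPERTY"))
    role <- if (any(grepl("role\\s*=\\s*target", props))) "target" else "feature"
    bn_variable(name, states, role)
  })
  defs <- xml2::xml_find_all(doc, ".//DEFINITION")
  arcs <- list()
  cpt_spec <- lapply(defs, function(dn) {
    child <- xml2::xml_text(xml2::xml_find_first(dn, "./FOR"))
    parents <- xml2::xml_text(xml2::xml_find_all(dn, "./GIVEN"))
    tab <- as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(dn, "./TABLE"))), "\\s+")[[1L]])
    list(child = child, parents = parents, tab = tab)
  })
  for (cs in cpt_spec) for (p in cs$parents) arcs[[length(arcs) + 1L]] <- c(p, cs$child)
  s <- bn_structure(vars, if (length(arcs) > 0L) arcs else NULL)
  cpts <- lapply(cpt_spec, function(cs) {
    cc <- length(s$variables[[cs$child]]$states)
    bn_cpt(cs$child, cs$parents, matrix(cs$tab, ncol = cc, byrow = TRUE))
  })
  bayesian_network(s, cpts)
}
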