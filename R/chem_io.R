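#' Structure input/output
#'
#' Parsing goes through OpenBabel (via ChemmineOB) for SMILES and InChI;
#' the resulting V2000 molblock is read into a [molgraph]. Aromatic systems
#' are kekulized by OpenBabel into a deterministic alternating-bond
#' assignment; bond type 4 (aromatic) appearing in user-supplied SDF files
#' is kept as order 1.5. Stereochemistry (wedge flags, chiral flags, InChI
#' stereo layers) is never read, so all stereoisomers of one constitution
#' yield the same graph.
#'
#' @name chem_io
NULL

# --- V2000 molblock <-> molgraph ------------------------------------------
# Charge codes in the atom block's legacy charge field.
.mdl_charge <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

# Read one V2000 connection table (character vector of lines, starting at
# the title line). Fixed-width fields per the CTfile spec, so >99-atom
# records parse correctly.
molblock_to_molgraph <- function(lines) {
  if (length(lines) < 4) stop("truncated molblock")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("unreadable molblock counts line")
  if (length(lines) < 4 + na + nb) stop("truncated molblock")
  atom_lines <- lines[4 + seq_len(na)]
  element <- trimws(substr(atom_lines, 32, 34))
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge <- unname(.mdl_charge[as.character(code)])
  charge[is.na(charge)] <- 0L
  bonds <- NULL
  if (nb > 0) {
    bond_lines <- lines[4 + na + seq_len(nb)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bt <- as.integer(substr(bond_lines, 7, 9))
    order <- ifelse(bt == 4, 1.5, as.numeric(bt))
    bonds <- data.frame(i = bi, j = bj, order = order)
  }
  # "M  CHG" property lines supersede the legacy charge field
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
      nent <- f[1]
      for (k in seq_len(nent)) charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  molgraph(data.frame(element = element, charge = charge), bonds)
}

# Write a molgraph as a V2000 molblock (coordinates zeroed; charges as
# "M  CHG"). Aromatic 1.5 orders become bond type 4.
molgraph_to_molblock <- function(g, title = "") {
  n <- n_atoms(g); nb <- nrow(g$bonds)
  head <- c(title, "  skeletax", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$atoms$element)
  bonds <- character(0)
  if (nb) {
    bt <- ifelse(g$bonds$order == 1.5, 4L, as.integer(g$bonds$order))
    bonds <- sprintf("%3d%3d%3d  0  0  0  0", g$bonds$i, g$bonds$j, bt)
  }
  props <- character(0)
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) {
    props <- vapply(split(chg, ceiling(seq_along(chg) / 8)), function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, g$atoms$charge[ix]), collapse = ""))
    }, character(1))
  }
  c(head, atoms, bonds, props, "M  END")
}

# --- parsing ---------------------------------------------------------------

#' Parse a structure string into a molecular graph
#'
#' @param text a SMILES or InChI string.
#' @param format `"smiles"` or `"inchi"`.
#' @return a [molgraph]. Unparsable input raises a condition of class
#'   `skeletax_parse_error` naming the offending text, so callers can log
#'   and skip rather than abort.
#' @examples
#' g <- parse_structure("CC(C)=O", "smiles")   # acetone: 4 atoms, one C=O
#' @export
parse_structure <- function(text, format = c("smiles", "inchi")) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop(parse_error(text, "empty structure string"))
  from <- c(smiles = "SMI", inchi = "INCHI")[[format]]
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, "SDF",
                                               paste0(trimws(text), "\n"))),
    error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4 || !grepl("V2000", lines[4]))
    stop(parse_error(text, "unparsable structure"))
  g <- tryCatch(molblock_to_molgraph(lines),
                error = function(e) stop(parse_error(text, conditionMessage(e))))
  if (n_atoms(g) == 0) stop(parse_error(text, "no atoms"))
  g
}

parse_error <- function(text, msg) {
  structure(class = c("skeletax_parse_error", "error", "condition"),
            list(message = sprintf("%s: %s", msg,
                                   substr(paste(text, collapse = " "), 1, 80)),
                 call = NULL, text = text))
}

#' Standardize a molecular graph
#'
#' Collapses any explicit hydrogens, drops isotope labels (never stored),
#' normalizes bond storage, and keeps formal charges on atoms (they are
#' never used by skeleton or pattern logic). Stereochemistry is already
#' absent from the graph representation. Multi-component inputs (salts)
#' stay as one graph with several connected components. Idempotent.
#'
#' @param graph a [molgraph].
#' @return a standardized [molgraph].
#' @export
standardize <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  molgraph(graph$atoms, graph$bonds)
}

#' Read compound structures from a file
#'
#' Readers for the three supported layouts: SMILES list and InChI list (one
#' record per line, optional tab-separated id as the second column), and SDF
#' (V2000, records split on `$$$$`, id taken from the title line when
#' present). Records whose structure fails to parse are kept with a `NULL`
#' graph and the error message in `parse_error`; the reader reports how many
#' were skipped rather than aborting.
#'
#' @param path input file.
#' @param format one of `"smiles"`, `"inchi"`, `"sdf"`.
#' @param source_db database tag stored on every record.
#' @return list of compound records (lists with `compound_id`, `name`,
#'   `structure_text`, `graph`, `parse_error`, `source_db`, `taxa`).
#' @export
read_structures <- function(path, format = c("smiles", "inchi", "sdf"),
                            source_db = "synthetic") {
  format <- match.arg(format)
  records <- list()
  if (format %in% c("smiles", "inchi")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (k in seq_along(lines)) {
      f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
      id <- if (length(f) >= 2 && nzchar(trimws(f[2]))) trimws(f[2]) else
        sprintf("cpd%04d", k)
      records[[k]] <- compound_record(id, f[1], format, source_db)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    starts <- c(1, which(lines == "$$$$") + 1)
    starts <- starts[starts <= length(lines)]
    ends <- c(which(lines == "$$$$") - 1, length(lines))
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:ends[k]]
      if (!any(nzchar(trimws(block)))) next
      id <- trimws(block[1])
      if (!nzchar(id)) id <- sprintf("cpd%04d", k)
      g <- tryCatch(standardize(molblock_to_molgraph(block)),
                    error = function(e) e)
      rec <- list(compound_id = id, name = id,
                  structure_text = paste(block, collapse = "\n"),
                  graph = if (inherits(g, "error")) NULL else g,
                  parse_error = if (inherits(g, "error"))
                    conditionMessage(g) else NA_character_,
                  source_db = source_db, taxa = character(0))
      records[[length(records) + 1]] <- rec
    }
  }
  ids <- vapply(records, `[[`, "", "compound_id")
  if (anyDuplicated(ids)) stop("duplicate compound_id in input: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n_bad <- sum(vapply(records, function(r) is.null(r$graph), logical(1)))
  if (n_bad) message(sprintf("skipped %d unparsable record(s)", n_bad))
  records
}

compound_record <- function(id, text, format, source_db, name = id,
                            taxa = character(0)) {
  g <- tryCatch(standardize(parse_structure(text, format)),
                error = function(e) e)
  list(compound_id = id, name = name, structure_text = text,
       graph = if (inherits(g, "error")) NULL else g,
       parse_error = if (inherits(g, "error")) conditionMessage(g) else
         NA_character_,
       source_db = source_db, taxa = taxa)
}

#' Convert a molecular graph to a SMILES string
#'
#' Serialization goes back through OpenBabel from a V2000 molblock.
#'
#' @param g a [molgraph].
#' @return canonical SMILES string.
#' @export
molgraph_to_smiles <- function(g) {
  mb <- paste(c(molgraph_to_molblock(g), "$$$$"), collapse = "\n")
  smi <- ChemmineOB::convertFormat("SDF", "CAN", paste0(mb, "\n"))
  out <- trimws(strsplit(smi, "[\t\n]")[[1]][1])
  if (!nzchar(out)) stop("SMILES serialization failed")
  out
}

# --- tables ----------------------------------------------------------------

#' Write a table of records to CSV
#'
#' Accepts a data.frame or a list of records sharing one schema (same field
#' names in the same order); list columns are collapsed with `;`. The CSV
#' has a header and a stable column order and round-trips losslessly
#' through [utils::read.csv()] for atomic fields.
#'
#' @param records data.frame or homogeneous list of named lists.
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    stopifnot(is.list(records))
    if (length(records)) {
      schemas <- lapply(records, names)
      if (!all(vapply(schemas, identical, logical(1), schemas[[1]])))
        stop("records have mixed schemas")
      df <- do.call(rbind, lapply(records, function(r) {
        r <- r[vapply(r, is.atomic, logical(1))]  # graphs etc. don't go to CSV
        as.data.frame(lapply(r, function(v) {
          if (length(v) != 1) paste(v, collapse = ";") else v
        }), stringsAsFactors = FALSE)
      }))
    } else {
      df <- data.frame()
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
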