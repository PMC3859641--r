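# PDB input/output and biological-assembly construction.
#
# File-format parsing is delegated to bio3d::read.pdb; this layer enforces
# the dataset conventions used throughout the analysis: first NMR model only,
# first alternate location only, hydrogens removed, optional restoration of
# MODRES-annotated modified residues to their parent standard residue, and
# rejection of insertion codes.

pdb_text_to_file <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), tf)
  tf
}

# MODRES records: modified residue -> parent standard residue.
parse_modres <- function(lines) {
  ml <- lines[startsWith(lines, "MODRES")]
  if (length(ml) == 0) {
    return(tibble(chain_id = character(), res_number = integer(),
                  resid3 = character(), std_resid3 = character()))
  }
  tibble(
    chain_id = trimws(substr(ml, 17, 17)),
    res_number = as.integer(trimws(substr(ml, 19, 22))),
    resid3 = trimws(substr(ml, 13, 15)),
    std_resid3 = trimws(substr(ml, 25, 27))
  ) |> filter(.data$std_resid3 %in% names(AA3))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into a [structure_model()]. Only the first NMR
#' model and the first encountered alternate location of each atom are kept;
#' hydrogen (and deuterium) atoms and waters are removed. Hetero atoms other
#' than water are retained with `het = TRUE` so that ligand distances can be
#' computed downstream. With `restore_modified = TRUE`, HETATM residues that
#' MODRES records map to a standard residue are restored as ordinary polymer
#' residues under their parent amino-acid code.
#'
#' @param pdb Path to a PDB file, or PDB-format text.
#' @param chain Optional chain identifier(s) to keep.
#' @param restore_modified Restore MODRES-annotated modified residues.
#' @param source_id Identifier stored on the model; defaults to the file name.
#' @return A [structure_model()]. REMARK 350 assembly transforms, when
#'   present, are attached as attribute `"biomt"` (see
#'   [assembly_transforms()]).
#' @export
parse_structure <- function(pdb, chain = NULL, restore_modified = FALSE,
                            source_id = NULL) {
  path <- pdb_text_to_file(pdb)
  source_id <- source_id %||% sub("\\.pdb$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  p <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("no parsable ATOM records in '", source_id,
                                     "': ", conditionMessage(e)))
  )
  at <- as_tibble(p$atom)
  if (!is.null(chain)) at <- filter(at, .data$chain %in% !!chain)
  if (nrow(filter(at, .data$type == "ATOM")) == 0) {
    abort(paste0("no parsable ATOM records for chain ",
                 paste(chain %||% "(any)", collapse = ","),
                 " in '", source_id, "'"))
  }
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported; renumber the structure first")
  }

  modres <- parse_modres(lines)
  if (restore_modified && nrow(modres) > 0) {
    hit <- paste(at$chain, at$resno, at$resid) %in%
      paste(modres$chain_id, modres$res_number, modres$resid3)
    std <- setNames(modres$std_resid3,
                    paste(modres$chain_id, modres$res_number, modres$resid3))
    at$resid[hit] <- std[paste(at$chain, at$resno, at$resid)[hit]]
    at$type[hit] <- "ATOM"
  }

  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | elem == ""
  elem[no_elem] <- substr(gsub("[^A-Za-z]", "", at$elety[no_elem]), 1, 1)
  at$element <- elem

  at <- at |>
    filter(!.data$element %in% c("H", "D"), .data$resid != "HOH") |>
    # first encountered alternate location per (chain, residue, atom)
    group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    slice(1) |>
    ungroup()

  het <- at$type == "HETATM"
  # a residue number must not carry two different residue codes
  amb <- at |>
    filter(!het) |>
    distinct(.data$chain, .data$resno, .data$resid) |>
    count(.data$chain, .data$resno) |>
    filter(.data$n > 1)
  if (nrow(amb) > 0) {
    abort(paste0("ambiguous residue identity at: ",
                 paste(amb$chain, amb$resno, collapse = ", ")))
  }

  structure_model(
    tibble(
      chain_id = at$chain, res_number = at$resno,
      aa = ifelse(het, NA_character_, aa321(at$resid)),
      resid3 = at$resid, atom_name = at$elety, element = at$element,
      x = at$x, y = at$y, z = at$z, het = het
    ),
    source_id = source_id
  ) -> model
  attr(model, "biomt") <- parse_biomt(lines)
  model
}

#' Write a structure model to PDB format
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  # PDB chain identifiers are single characters; map longer assembly-copy
  # identifiers onto unused letters for serialisation.
  ch <- unique(model$chain_id)
  pdb_ch <- ch
  long <- nchar(ch) > 1
  if (any(long)) {
    pool <- setdiff(c(LETTERS, letters, 0:9), ch[!long])
    pdb_ch[long] <- pool[seq_len(sum(long))]
  }
  chain_map <- setNames(pdb_ch, ch)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(model))),
    type = ifelse(model$het, "HETATM", "ATOM"),
    resno = model$res_number,
    resid = model$resid3,
    eleno = seq_len(nrow(model)),
    elety = model$atom_name,
    chain = unname(chain_map[model$chain_id]),
    elesy = model$element
  )
  invisible(path)
}

#' Parse REMARK 350 biological-assembly transforms
#'
#' @param pdb Path to a PDB file, PDB text, or a character vector of lines.
#' @return Tibble with one row per (biomolecule, transform): columns
#'   `biomolecule`, `transform`, `target_chains` (list), `rotation`
#'   (list of 3x3 matrices) and `translation` (list of length-3 vectors).
#' @export
assembly_transforms <- function(pdb) {
  lines <- if (length(pdb) > 1) pdb else readLines(pdb_text_to_file(pdb), warn = FALSE)
  parse_biomt(lines)
}

parse_biomt <- function(lines) {
  rl <- lines[startsWith(lines, "REMARK 350")]
  empty <- tibble(biomolecule = integer(), transform = integer(),
                  target_chains = list(), rotation = list(), translation = list())
  if (length(rl) == 0) return(empty)
  out <- list(); biomol <- NA_integer_; chains <- character()
  rows <- list() # key: biomol.transform -> accumulating 3x4
  for (ln in rl) {
    if (grepl("BIOMOLECULE:", ln)) {
      biomol <- as.integer(trimws(sub(".*BIOMOLECULE:", "", ln)))
      chains <- character()
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", ln) ||
               grepl("AND CHAINS:", ln)) {
      cs <- trimws(strsplit(sub(".*CHAINS:", "", ln), ",")[[1]])
      chains <- c(chains, cs[cs != ""])
    } else if (grepl("BIOMT[123]", ln)) {
      m <- regmatches(ln, regexec(
        "BIOMT([123])\\s+(\\d+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)", ln))[[1]]
      if (length(m) == 0) next
      rowi <- as.integer(m[2]); tr <- as.integer(m[3])
      key <- paste(biomol, tr, sep = ".")
      if (is.null(rows[[key]])) {
        rows[[key]] <- list(mat = matrix(NA_real_, 3, 4),
                            biomolecule = biomol, transform = tr,
                            chains = chains)
      }
      rows[[key]]$mat[rowi, ] <- as.numeric(m[4:7])
      rows[[key]]$chains <- chains
    }
  }
  if (length(rows) == 0) return(empty)
  purrr::map(rows, function(r) tibble(
    biomolecule = r$biomolecule, transform = r$transform,
    target_chains = list(r$chains),
    rotation = list(r$mat[, 1:3, drop = FALSE]),
    translation = list(r$mat[, 4])
  )) |>
    list_rbind() |>
    arrange(.data$biomolecule, .data$transform)
}

is_identity_transform <- function(rotation, translation, tol = 1e-6) {
  max(abs(rotation - diag(3))) <= tol && max(abs(translation)) <= tol
}

#' Build a biological assembly from transforms
#'
#' Applies each rotation/translation to its target chains and collects the
#' copies into one model. Copies produced by a non-identity transform `i` are
#' renamed `<chain>.<i>`; the identity transform keeps the original chain
#' identifier, so the monomer chains remain addressable inside the assembly.
#'
#' @param model A [structure_model()].
#' @param transforms Tibble as returned by [assembly_transforms()]. Defaults
#'   to the transforms attached to `model` at parse time.
#' @param tol Orthonormality tolerance for rotation validation.
#' @return A [structure_model()] of the assembly.
#' @export
apply_assembly <- function(model, transforms = attr(model, "biomt"),
                           tol = 1e-6) {
  if (is.null(transforms) || nrow(transforms) == 0) {
    abort("no assembly transforms supplied and none attached to the model")
  }
  copies <- pmap(transforms, function(biomolecule, transform, target_chains,
                                      rotation, translation, ...) {
    if (max(abs(crossprod(rotation) - diag(3))) > tol) {
      abort(sprintf("transform %d: rotation matrix is not orthonormal", transform))
    }
    missing <- setdiff(target_chains, unique(model$chain_id))
    if (length(missing) > 0) {
      abort(paste0("transform targets absent chains: ",
                   paste(missing, collapse = ", ")))
    }
    sub <- model[model$chain_id %in% target_chains, ]
    xyz <- coords(sub) %*% t(rotation) + rep(translation, each = nrow(sub))
    sub$x <- xyz[, 1]; sub$y <- xyz[, 2]; sub$z <- xyz[, 3]
    if (!is_identity_transform(rotation, translation, tol)) {
      sub$chain_id <- paste0(sub$chain_id, ".", transform)
    }
    as_tibble(sub)
  })
  structure_model(list_rbind(copies),
                  source_id = paste0(attr(model, "source_id"), "_assembly"))
}
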