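# Readers and writers for the package's plain-text formats.  All readers
# validate and reject malformed input rather than silently coercing; every
# writer/reader pair round-trips.

#' Write a scan set to disk
#'
#' One file per scan (commented header with time, rotor speed, temperature,
#' pathlength and wavelength, then tab-separated radius/signal rows) plus a
#' `manifest.tsv` grouping the files into a set.
#'
#' @param ss a [scan_set].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param wavelength_nm detection wavelength recorded in headers.
#' @return invisibly, the manifest path.
#' @export
write_scan_set <- function(ss, dir, prefix = "scan", wavelength_nm = 280) {
  stopifnot(inherits(ss, "scan_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(ss$signal))
  for (i in seq_len(nrow(ss$signal))) {
    f <- file.path(dir, sprintf("%s_%04d.tsv", prefix, i))
    files[i] <- basename(f)
    hdr <- c(sprintf("# sv-scan %d", i),
             sprintf("# time_s: %.6g", ss$times_s[i]),
             sprintf("# rpm: %.6g", ss$rpm),
             sprintf("# temperature_C: %.6g", ss$temperature_C),
             sprintf("# pathlength_mm: %.6g", ss$pathlength_mm),
             sprintf("# wavelength_nm: %.6g", wavelength_nm),
             "radius_cm\tsignal_AU")
    body <- sprintf("%.6f\t%.8g", ss$radii_cm, ss$signal[i, ])
    writeLines(c(hdr, body), f)
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(data.frame(file = files, time_s = ss$times_s,
                         set = if (nzchar(ss$label)) ss$label else "set1"),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

.read_scan_file <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr_lines, value = TRUE)
    if (length(m) != 1) stop("missing header field '", key, "' in ", path)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", m))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)][-1]  # drop column-name row
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed data rows in ", path)
  radius <- as.numeric(vapply(parts, `[`, "", 1))
  signal <- as.numeric(vapply(parts, `[`, "", 2))
  if (any(!is.finite(radius)) || any(!is.finite(signal)))
    stop("non-numeric radius or signal in ", path)
  bad <- which(diff(radius) <= 0)
  if (length(bad)) stop("radii not strictly increasing in ", path,
                        " at row ", bad[1] + 1)
  list(time_s = get("time_s"), rpm = get("rpm"),
       temperature_C = get("temperature_C"),
       pathlength_mm = get("pathlength_mm"),
       radius = radius, signal = signal)
}

#' Read scan sets from a manifest
#'
#' Reads the files listed in a `manifest.tsv` (see [write_scan_set]),
#' validates them (monotone radii, complete headers, consistent rotor
#' speeds within a set) and groups them into one [scan_set] per `set`
#' label.
#'
#' @param manifest path to the manifest, or a directory containing one.
#' @return a [scan_set], or a named list of them when the manifest spans
#'   several sets.
#' @export
read_scan_set <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- read.table(manifest, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("file", "set") %in% names(man)))
  dir <- dirname(manifest)
  sets <- lapply(split(man, man$set), function(grp) {
    scans <- lapply(file.path(dir, grp$file), .read_scan_file)
    rpm <- unique(vapply(scans, `[[`, 0, "rpm"))
    if (length(rpm) != 1) stop("mixed rotor speeds within set '",
                               grp$set[1], "'")
    radii <- scans[[1]]$radius
    for (s in scans) if (!isTRUE(all.equal(s$radius, radii)))
      stop("scans in a set must share a radial grid")
    ord <- order(vapply(scans, `[[`, 0, "time_s"))
    scans <- scans[ord]
    scan_set(times_s = vapply(scans, `[[`, 0, "time_s"),
             radii_cm = radii,
             signal = do.call(rbind, lapply(scans, `[[`, "signal")),
             rpm = rpm, temperature_C = scans[[1]]$temperature_C,
             pathlength_mm = scans[[1]]$pathlength_mm,
             label = grp$set[1])
  })
  if (length(sets) == 1) sets[[1]] else sets
}

#' Read a Beckman-style velocity scan (lenient dialect)
#'
#' Two-line header (free-text title, then a whitespace-separated numeric
#' line whose fields are taken as: type flag, temperature (C), rpm, time
#' (s), omega^2 t, wavelength (nm)), followed by radius/signal rows,
#' optionally with a third standard-deviation column.
#'
#' @param path scan file path.
#' @return list with `time_s`, `rpm`, `temperature_C`, `radius`, `signal`.
#' @export
read_scan_beckman <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a scan file: ", path)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(hdr) < 6) stop("unrecognized header line in ", path)
  num <- suppressWarnings(as.numeric(hdr[2:6]))
  if (any(!is.finite(num))) stop("unrecognized header line in ", path)
  rows <- strsplit(trimws(lines[-(1:2)]), "\\s+")
  rows <- rows[lengths(rows) >= 2]
  radius <- as.numeric(vapply(rows, `[`, "", 1))
  signal <- as.numeric(vapply(rows, `[`, "", 2))
  if (any(!is.finite(radius)) || any(!is.finite(signal)))
    stop("non-numeric data rows in ", path)
  if (any(diff(radius) <= 0)) stop("radii not strictly increasing in ", path)
  list(time_s = num[3], rpm = num[2], temperature_C = num[1],
       radius = radius, signal = signal, wavelength_nm = num[5])
}

# element from a PDB atom name when the element column is absent
.element_from_name <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  substr(n, 1, 1)
}

#' Read structure models into a trajectory ensemble
#'
#' Reads a PDB or multi-model PDB (each MODEL record becomes one frame),
#' converts Angstrom to nm, preserves chain ids and verbatim residue
#' numbering, and sets heavy-atom flags from the element (inferred from the
#' atom name when the element column is missing).  Only the first alternate
#' location is kept, with a warning.
#'
#' @param path PDB file.
#' @param expected_chains optional required number of chains; a mismatch is
#'   an error.
#' @return a [traj_ensemble].
#' @export
read_models <- function(path, expected_chains = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  rows <- which(pdb$atom$type %in% c("ATOM", "HETATM"))
  at <- pdb$atom[rows, ]
  has_alt <- !is.na(at$alt) & nzchar(at$alt)
  keep <- !has_alt | at$alt == "A"
  if (any(has_alt & at$alt != "A")) {
    warning("alternate locations present; keeping the first altloc")
  }
  at <- at[keep, ]
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) {
    message("element column missing for ", sum(miss),
            " atoms; inferring from atom names")
    elem[miss] <- .element_from_name(at$elety[miss])
  }
  chains <- unique(at$chain)
  if (!is.null(expected_chains) && length(chains) != expected_chains)
    stop("expected ", expected_chains, " chains, found ", length(chains))
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = at$resid, name = at$elety,
                      element = trimws(elem), stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); nat <- ncol(xyz) / 3
  arr <- array(0, c(nf, nat, 3))
  for (f in seq_len(nf))
    arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  arr <- arr[, rows[keep], , drop = FALSE]
  traj_ensemble(atoms, arr, unit = "angstrom")
}

#' Write a trajectory ensemble as a (multi-model) PDB
#'
#' @param traj a [traj_ensemble].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_models <- function(traj, path) {
  a <- traj$atoms
  nf <- dim(traj$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(a))) {
      xyz <- traj$xyz[f, i, ] * 10  # nm -> Angstrom
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, ifelse(nchar(a$name[i]) < 4, paste0(" ", a$name[i]), a$name[i]),
        a$resname[i], a$chain[i], a$resno[i], xyz[1], xyz[2], xyz[3],
        a$element[i]), con)
    }
    writeLines("TER", con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# 32-bit polynomial rolling hash for provenance stamping of configurations
.confhash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 4294967291
  sprintf("%08x", h)
}

#' Write an analysis report
#'
#' Serializes results to JSON (stable field order, fixed floating-point
#' precision) or TSV, stamped with the package version, the seed, and a
#' hash of the configuration for provenance.  Identical results produce
#' byte-identical files.
#'
#' @param results a named list (JSON) or data.frame (TSV).
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @param seed seed recorded in the provenance block.
#' @param config configuration object hashed into the provenance block.
#' @return invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("json", "tsv"),
                         seed = NA_integer_, config = NULL) {
  format <- match.arg(format)
  prov <- list(package = "helimer",
               version = as.character(packageVersion("helimer")),
               seed = seed, config_hash = .confhash(config))
  if (format == "json") {
    jsonlite::write_json(list(provenance = prov, results = results), path,
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  } else {
    stopifnot(is.data.frame(results))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# helimer %s seed %s config %s", prov$version,
                       prov$seed, prov$config_hash), con)
    write.table(format(results, digits = 10), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
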