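# Fixtures built in code: hand-written PDB records and tiny models.

# One fixed-width PDB ATOM record (altloc at column 17)
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          altloc = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), altloc, resid, chain, resno,
          x, y, z, 1.0, 0.0, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Minimal hand-built model: coords is a list of chain -> data.frame(resno,
# resid, x, y, z)
toy_structure <- function(coords, model_id = "toy") {
  rows <- do.call(rbind, lapply(names(coords), function(ch) {
    d <- coords[[ch]]
    data.frame(chain = ch, resno = d$resno,
               resid = if (is.null(d$resid)) "LYS" else d$resid,
               elety = "CA", x = d$x, y = d$y, z = d$z, element = "C",
               stringsAsFactors = FALSE)
  }))
  xl_structure(rows, model_id = model_id)
}

# Canonical toy CSM table
toy_csms <- function(protein_a, position_a, protein_b, position_b,
                     passes_fdr = TRUE) {
  n <- length(protein_a)
  out <- data.frame(csm_id = sprintf("c%03d", seq_len(n)),
                    replicate = rep_len("rep1", n),
                    protein_a = protein_a, position_a = position_a,
                    protein_b = protein_b, position_b = position_b,
                    score = rep_len(100, n),
                    passes_fdr = rep_len(passes_fdr, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("xl_csms", "data.frame")
  out
}
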