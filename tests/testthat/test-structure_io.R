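test_that("parse_complex counts residues and ligand heavy atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f)
  cx <- parse_complex(f)
  expect_s3_class(cx, "complex_structure")
  expect_equal(nrow(cx$protein), 3)
  expect_equal(nrow(cx$ligand), 2)
  expect_equal(cx$ligand_name, "LIG")
})

test_that("waters are excluded from ligand candidacy", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f1)
  write_mini_pdb(f2, add_water = TRUE)
  cx1 <- parse_complex(f1); cx2 <- parse_complex(f2)
  expect_equal(nrow(cx2$ligand), nrow(cx1$ligand))
  expect_equal(cx2$ligand_name, cx1$ligand_name)
  expect_equal(nrow(cx2$protein), nrow(cx1$protein))
})

test_that("ambiguous ligand selection errors and names both candidates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, second_ligand = TRUE)
  err <- expect_error(parse_complex(f), "ambiguous ligand")
  expect_match(conditionMessage(err), "LIG")
  expect_match(conditionMessage(err), "XYZ")
  cx <- parse_complex(f, ligand = "XYZ")
  expect_equal(cx$ligand_name, "XYZ")
  expect_equal(nrow(cx$ligand), 1)
})

test_that("files with no ligand candidate error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
             pdb_atom_line(2, "O", "HOH", "W", 2, 5, 5, 5,
                           record = "HETATM", element = "O"), "END")
  writeLines(lines, f)
  expect_error(parse_complex(f), "no ligand")
})

test_that("pocket localization follows the distance rule", {
  prot <- data.frame(elety = "CA", resid = "ALA", resno = 1,
                     x = 4, y = 0, z = 0, element = "C")
  lig <- data.frame(elety = "C1", x = 0, y = 0, z = 0, element = "C")
  cx <- build_cx(prot, lig)
  expect_equal(localize_pocket(cx, 10), 1L)
  expect_equal(localize_pocket(cx, 3), integer(0))
  expect_error(localize_pocket(cx, -1), "radius")
})

test_that("pocket equals a brute-force all-pairs scan and is monotone in radius", {
  mc <- make_complex(six_type_spec())
  cx <- mc$cx
  for (radius in c(4, 6, 8, 12)) {
    # oracle: independent double loop over residues and ligand atoms
    expected <- sort(unique(unlist(lapply(cx$protein$j, function(j) {
      pa <- cx$prot_atoms[cx$prot_atoms$j == j, ]
      for (a in seq_len(nrow(pa))) for (i in seq_len(nrow(cx$ligand))) {
        d <- sqrt((pa$x[a] - cx$ligand$x[i])^2 +
                  (pa$y[a] - cx$ligand$y[i])^2 +
                  (pa$z[a] - cx$ligand$z[i])^2)
        if (d <= radius) return(j)
      }
      NULL
    }))))
    expect_equal(localize_pocket(cx, radius), as.integer(expected))
  }
  radii <- c(2, 4, 6, 8, 10, 20)
  pockets <- lapply(radii, localize_pocket, cx = cx)
  for (k in seq_len(length(radii) - 1))
    expect_true(all(pockets[[k]] %in% pockets[[k + 1]]))
})

test_that("sequence extraction maps 3-letter names, modified residues and unknowns", {
  prot <- data.frame(
    elety = rep("CA", 5), resid = c("ALA", "GLY", "TRP", "MSE", "UNK"),
    resno = 1:5, x = (0:4) * 4, y = 0, z = 0, element = "C")
  lig <- data.frame(elety = "C1", x = 0, y = 0, z = 5, element = "C")
  ps <- extract_sequence(build_cx(prot, lig))
  expect_equal(ps$sequence, "AGWMX")
  # index_map round trip: pos -> structure residue -> pos is the identity
  im <- ps$index_map
  back <- vapply(seq_len(nrow(im)), function(p) {
    row <- im[im$pos == p, ]
    im$pos[im$chain == row$chain & im$resno == row$resno &
             im$insert == row$insert]
  }, integer(1))
  expect_equal(back, seq_len(nrow(im)))
  expect_false(anyDuplicated(paste(im$chain, im$resno, im$insert)) > 0)
})

test_that("re-serializing and re-parsing preserves residue and atom counts", {
  mc <- make_complex(six_type_spec())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex(mc$cx, f)
  cx2 <- parse_complex(f)
  expect_equal(nrow(cx2$protein), nrow(mc$cx$protein))
  expect_equal(nrow(cx2$prot_atoms), nrow(mc$cx$prot_atoms))
  expect_equal(nrow(cx2$ligand), nrow(mc$cx$ligand))
  expect_equal(cx2$protein$resid, mc$cx$protein$resid)
  # annotation of the round-tripped structure is unchanged
  a1 <- annotate_complex(mc$cx); a2 <- annotate_complex(cx2)
  expect_equal(a2$contacts[, c("type", "i", "j")],
               a1$contacts[, c("type", "i", "j")])
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0, occ = 0.3, alt = "A",
                  element = "C"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 9.5, 0, 0, occ = 0.7, alt = "B",
                  element = "C"),
    pdb_atom_line(4, "C1", "LIG", "B", 90, 3, 3, 3, record = "HETATM",
                  element = "C"),
    "END")
  writeLines(lines, f)
  cx <- parse_complex(f)
  ca <- cx$prot_atoms[cx$prot_atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9.5)
})

test_that("complex manifest reports identity, sizes and pocket", {
  mc <- make_complex(six_type_spec())
  mf <- complex_manifest(mc$cx, radius = 10)
  expect_equal(mf$m, 12)
  expect_equal(mf$n, 12)
  expect_true(all(unique(mc$spec$contacts$j) %in% mf$pocket_residues))
})
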