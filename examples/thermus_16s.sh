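#!/bin/sh
# Example workflow: compare 16S ribosomal RNA structures of Thermus
# thermophilus solved with different bound inhibitors.  Download the
# Bpseq files yourself from the RNA STRAND database (www.rnasoft.ca/strand;
# e.g. accessions PDB_00478, PDB_00408, PDB_00436, PDB_00438, PDB_00589),
# place them in the working directory, then:
#
# 1. Global view: the shadow isolates the pseudoknot skeleton.  Identical
#    shadows across the molecules mean the inhibitors act locally.
for f in PDB_*.bpseq; do
  echo "== shadow of $f =="
  relmat matrix "$f" --level shadow
done

# 2. Intermediate view: compare cores of a subregion (here the classic
#    800-900 window, cut out beforehand with your favourite tool) and
#    search a pattern in them.
# relmat match --target PDB_00478_800_900.bpseq --pattern pattern.tsv --level core
#
# Not executed by the test suite: requires external downloads.
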