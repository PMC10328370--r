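"""Regenerate the frozen nearest-neighbor Tm reference fixture.

Writes tests/testthat/tm-oracle.tsv: 200 random 20-40-mers plus a few fixed
sequences, with melting temperatures from Bio.SeqUtils.MeltingTemp.Tm_NN at
its documented defaults (Allawi & SantaLucia 1997 table, dnac1=dnac2=25 nM,
Na=50 mM, salt correction method 5). Run from the repository root.
"""
import random
from Bio.SeqUtils import MeltingTemp as mt

random.seed(20230707)
rows = []
fixed = [
    "ACGTACGTACGTACGTACGT",
    "GCGCGCGCGCGCGCGCGCGC",
    "ATATATATATATATATATAT",
    "AAGCTTGGCACTGGCCGTCGTTTTAC",
]
s30 = "ACCTGAAGTTCATCTGCACCACCGGCAAGC"
fixed += [s30, s30[:14] + "G" + s30[15:]]  # internal A->G pair
for s in fixed:
    rows.append((s, mt.Tm_NN(s)))
for _ in range(200):
    L = random.randint(20, 40)
    s = "".join(random.choice("ACGT") for _ in range(L))
    rows.append((s, mt.Tm_NN(s)))
with open("tests/testthat/tm-oracle.tsv", "w") as fh:
    fh.write("seq\ttm\n")
    for s, t in rows:
        fh.write(f"{s}\t{t:.10f}\n")
print(f"wrote {len(rows)} rows")
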