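"""Deterministic 3D embedding of SMILES via RDKit ETKDG.

Reads lines "SMILES<space>name" on stdin, writes one SDF block per valid
input to stdout. The embedding seed is fixed per molecule, so output
depends only on the molecule itself, never on batch composition or wall
clock.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smi, name):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = 42
    if AllChem.EmbedMolecule(mol, params) != 0:
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(mol, params) != 0:
            return None
    try:
        AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
    except Exception:
        pass
    mol.SetProp("_Name", name)
    return Chem.MolToMolBlock(mol)


def main():
    for line in sys.stdin:
        parts = line.split()
        if not parts:
            continue
        name = parts[1] if len(parts) > 1 else parts[0]
        block = embed(parts[0], name)
        if block is not None:
            sys.stdout.write(block + "$$$$\n")
        else:
            sys.stderr.write("embed failed: %s\n" % parts[0])


if __name__ == "__main__":
    main()
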