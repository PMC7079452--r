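"""Batch canonicalization-oracle backend.

Reads a JSON array of requests on stdin, writes a JSON array of responses
on stdout. Each request: {"op": str, "smiles": str, "arg": int|null}.
Ops: canonical | variant (arg = seed) | rooted (arg = 0-based atom index)
| natoms. Errors are returned per-item as {"error": message}.
"""
import json
import random
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def handle(req):
    op = req["op"]
    mol = Chem.MolFromSmiles(req["smiles"])
    if mol is None:
        return {"error": "unparseable SMILES: %s" % req["smiles"]}
    if op == "canonical":
        return {"smiles": Chem.MolToSmiles(mol)}
    if op == "natoms":
        return {"n": mol.GetNumAtoms()}
    if op == "variant":
        rng = random.Random(int(req["arg"]))
        perm = list(range(mol.GetNumAtoms()))
        rng.shuffle(perm)
        mol = Chem.RenumberAtoms(mol, perm)
        return {"smiles": Chem.MolToSmiles(mol, canonical=False)}
    if op == "rooted":
        idx = int(req["arg"])
        if idx < 0 or idx >= mol.GetNumAtoms():
            return {"error": "atom index out of range"}
        smi = Chem.MolToSmiles(mol, canonical=False, rootedAtAtom=idx)
        order = list(map(int, mol.GetProp("_smilesAtomOutputOrder")
                         .strip("[],").split(",")))
        return {"smiles": smi, "order": order}
    return {"error": "unknown op: %s" % op}


def main():
    reqs = json.load(sys.stdin)
    json.dump([handle(r) for r in reqs], sys.stdout)


if __name__ == "__main__":
    main()
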