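"""Sanitization validity and MMFF94 potential energies for an SDF file.

Reads an SDF (records parsed without sanitization so broken molecules are
still examined), attempts default RDKit sanitization on each record, and for
valid records computes the MMFF94 potential energy of the stored
conformation. Emits one JSON array on stdout: per record an object
{"valid": bool, "energy": float|null, "error": str|null}.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def evaluate(path):
    out = []
    supplier = Chem.SDMolSupplier(path, sanitize=False, removeHs=False)
    for mol in supplier:
        rec = {"valid": False, "energy": None, "error": None}
        if mol is None:
            rec["error"] = "unparsable record"
            out.append(rec)
            continue
        try:
            Chem.SanitizeMol(mol)
            rec["valid"] = True
        except Exception as exc:  # sanitization failure = invalid, not error
            rec["error"] = str(exc)
            out.append(rec)
            continue
        try:
            props = AllChem.MMFFGetMoleculeProperties(mol)
            if props is not None and mol.GetNumConformers() > 0:
                ff = AllChem.MMFFGetMoleculeForceField(mol, props)
                if ff is not None:
                    rec["energy"] = ff.CalcEnergy()
        except Exception as exc:
            rec["error"] = "energy: " + str(exc)
        out.append(rec)
    return out


if __name__ == "__main__":
    json.dump(evaluate(sys.argv[1]), sys.stdout)
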