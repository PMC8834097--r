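control	sex	excluded	exclusion_reason
C01	F	FALSE	NA
C02	F	FALSE	NA
C03	F	FALSE	NA
C04	F	FALSE	NA
C05	F	FALSE	NA
C06	F	FALSE	NA
C07	F	FALSE	NA
C08	F	FALSE	NA
C09	F	FALSE	NA
C10	F	FALSE	NA
C11	F	TRUE	surgical procedure in the week before sample collection
C12	M	FALSE	NA
C13	M	FALSE	NA
C14	M	FALSE	NA
C15	M	FALSE	NA
C16	M	FALSE	NA
C17	M	FALSE	NA
C18	M	FALSE	NA
C19	M	FALSE	NA
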