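code,system,description
R45.851,ICD-10,Suicidal ideation
T14.91,ICD-10,Suicide attempt
Z91.5,ICD-10,Personal history of self-harm
X71,ICD-10,Intentional self-harm by drowning (range X71-X83)
X72,ICD-10,Intentional self-harm by handgun discharge
X73,ICD-10,Intentional self-harm by rifle/shotgun discharge
X74,ICD-10,Intentional self-harm by other firearm discharge
X75,ICD-10,Intentional self-harm by explosive material
X76,ICD-10,Intentional self-harm by smoke/fire/flames
X77,ICD-10,Intentional self-harm by steam/hot vapors/hot objects
X78,ICD-10,Intentional self-harm by sharp object
X79,ICD-10,Intentional self-harm by blunt object
X80,ICD-10,Intentional self-harm by jumping from a high place
X81,ICD-10,Intentional self-harm by jumping/lying in front of moving object
X82,ICD-10,Intentional self-harm by crashing of motor vehicle
X83,ICD-10,Intentional self-harm by other specified means
V62.84,ICD-9,Suicidal ideation
E950,ICD-9,Suicide by solid or liquid substances (range E950-E959)
E951,ICD-9,Suicide by gases in domestic use
E952,ICD-9,Suicide by other gases and vapors
E953,ICD-9,Suicide by hanging strangulation and suffocation
E954,ICD-9,Suicide by submersion
E955,ICD-9,Suicide by firearms and explosives
E956,ICD-9,Suicide by cutting and piercing instrument
E957,ICD-9,Suicide by jumping from high place
E958,ICD-9,Suicide by other and unspecified means
E959,ICD-9,Late effects of self-inflicted injury
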